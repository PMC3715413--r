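// Explicit-Euler integration of one maturation period (or a fraction of
// one) for the cisternal transport model.  Mirrors the R reference
// implementation in R/dynamics.R; equivalence is asserted in the test
// suite.  Role codes (0-based, fixed order): 0 t_snare_alpha,
// 1 v_snare_alpha, 2 t_snare_beta, 3 v_snare_beta, 4 er_v_snare,
// 5 passive_cargo.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Weights {
  std::vector<double> W;       // N x N, column-major, self fold-in on diagonal
  std::vector<double> w_er;    // per donor
  std::vector<double> outfrac; // per donor: total non-self weight
};

// Fusion weights for every donor.  Each local donor has three compartment
// slots (cis face / self / trans face); a face with no neighbour falls
// back to the donor itself, or to the ER zeroth cisterna at the open cis
// end.  include_er == false computes the stack-internal weights used for
// the SNARE subsystem under er_cargo_only.
void fusion_weights_all(const NumericMatrix& C, const std::vector<double>& v,
                        int S, int N, int ia_t, int ia_v, int ib_t, int ib_v,
                        int ier, double T_ER, int topology, int er_access,
                        bool include_er, Weights& out) {
  out.W.assign((size_t)N * N, 0.0);
  out.w_er.assign(N, 0.0);
  out.outfrac.assign(N, 0.0);
  for (int i = 0; i < N; ++i) {
    double vA = ia_v >= 0 ? v[ia_v + (size_t)i * S] : 0.0;
    double vB = ib_v >= 0 ? v[ib_v + (size_t)i * S] : 0.0;
    double ver = ier >= 0 ? v[ier + (size_t)i * S] : vA + vB;
    double e_i = ver * T_ER;
    bool er_ok = include_er &&
      ((er_access == 2) || (er_access == 1 && i == 0));

    int j_lo, j_hi;
    if (topology == 0) {
      j_lo = std::max(0, i - 1);
      j_hi = std::min(N - 1, i + 1);
    } else {
      j_lo = 0;
      j_hi = N - 1;
    }
    double aff_sum = 0.0, self_aff = 0.0, extra_self = 0.0, er_aff = 0.0;
    for (int j = j_lo; j <= j_hi; ++j) {
      double a = 0.0;
      if (ia_t >= 0) a += vA * C(ia_t, j);
      if (ib_t >= 0) a += vB * C(ib_t, j);
      out.W[i + (size_t)j * N] = a;
      aff_sum += a;
      if (j == i) self_aff = a;
    }
    if (topology == 0) {
      if (i == 0) {
        if (er_ok) er_aff = e_i; else extra_self = self_aff;
      } else if (er_ok) {
        er_aff = e_i;
      }
      if (i == N - 1) extra_self += self_aff;
    } else if (er_ok) {
      er_aff = e_i;
    }
    double den = aff_sum + extra_self + er_aff;
    if (den > 0.0) {
      for (int j = j_lo; j <= j_hi; ++j) out.W[i + (size_t)j * N] /= den;
      out.W[i + (size_t)i * N] += extra_self / den;
      out.w_er[i] = er_aff / den;
    } else {
      for (int j = j_lo; j <= j_hi; ++j) out.W[i + (size_t)j * N] = 0.0;
      out.w_er[i] = 0.0;
    }
    double of = out.w_er[i];
    for (int j = j_lo; j <= j_hi; ++j)
      if (j != i) of += out.W[i + (size_t)j * N];
    out.outfrac[i] = of;
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_integrate(NumericMatrix C_in, NumericVector K, NumericVector kappa,
                   IntegerVector role, double omega, double n_sites,
                   double T_ER,
                   int topology,      // 0 local, 1 unrestricted
                   int er_access,     // 0 none, 1 first_cisterna_only, 2 all
                   int sharing,       // 0 all, 1 by_class
                   int er_cargo_only, // 0 shared fate, 1 cargo-only ER
                   double dt, int n_steps) {
  const int S = C_in.nrow(), N = C_in.ncol();
  NumericMatrix C(clone(C_in));
  NumericVector er_acc(S), decay_acc(S);
  long clamps = 0;

  int ia_t = -1, ia_v = -1, ib_t = -1, ib_v = -1, ier = -1;
  for (int s = 0; s < S; ++s) {
    switch (role[s]) {
      case 0: ia_t = s; break;
      case 1: ia_v = s; break;
      case 2: ib_t = s; break;
      case 3: ib_v = s; break;
      case 4: ier = s; break;
      default: break;
    }
  }
  const bool split = er_cargo_only != 0 && er_access != 0;

  std::vector<double> v((size_t)S * N), dC((size_t)S * N);
  Weights w_cargo, w_snare;

  for (int step = 0; step < n_steps; ++step) {
    // vesicle loading
    if (sharing == 0) {
      for (int j = 0; j < N; ++j) {
        double denom = 1.0;
        for (int s = 0; s < S; ++s) denom += C(s, j) / K[s];
        for (int s = 0; s < S; ++s)
          v[s + (size_t)j * S] = n_sites * (C(s, j) / K[s]) / denom;
      }
    } else {
      for (int j = 0; j < N; ++j) {
        double denom = 1.0;
        for (int s = 0; s < S; ++s)
          if (role[s] == 5) denom += C(s, j) / K[s];
        for (int s = 0; s < S; ++s) {
          if (role[s] == 5)
            v[s + (size_t)j * S] = n_sites * (C(s, j) / K[s]) / denom;
          else
            v[s + (size_t)j * S] = n_sites * C(s, j) / (K[s] + C(s, j));
        }
      }
    }

    fusion_weights_all(C, v, S, N, ia_t, ia_v, ib_t, ib_v, ier, T_ER,
                       topology, er_access, true, w_cargo);
    if (split) {
      fusion_weights_all(C, v, S, N, ia_t, ia_v, ib_t, ib_v, ier, T_ER,
                         topology, er_access, false, w_snare);
    }

    std::fill(dC.begin(), dC.end(), 0.0);
    for (int i = 0; i < N; ++i) {
      int j_lo, j_hi;
      if (topology == 0) {
        j_lo = std::max(0, i - 1);
        j_hi = std::min(N - 1, i + 1);
      } else {
        j_lo = 0;
        j_hi = N - 1;
      }
      for (int s = 0; s < S; ++s) {
        const Weights& w = (split && role[s] != 5) ? w_snare : w_cargo;
        double vs = v[s + (size_t)i * S];
        dC[s + (size_t)i * S] -= omega * vs * w.outfrac[i];
        for (int j = j_lo; j <= j_hi; ++j)
          if (j != i)
            dC[s + (size_t)j * S] += omega * vs * w.W[i + (size_t)j * N];
        er_acc[s] += dt * omega * vs * w.w_er[i];
      }
    }
    for (int j = 0; j < N; ++j) {
      for (int s = 0; s < S; ++s) {
        double c = C(s, j);
        decay_acc[s] += dt * kappa[s] * c;
        double cn = c + dt * (dC[s + (size_t)j * S] - kappa[s] * c);
        if (cn < 0.0) { cn = 0.0; ++clamps; }
        C(s, j) = cn;
      }
    }
  }

  return List::create(
    _["C"] = C, _["er"] = er_acc, _["decayed"] = decay_acc,
    _["clamps"] = (double)clamps);
}
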