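#' Create the state container for a Golgi stack
#'
#' The state is the species-by-cisterna concentration matrix plus the phase
#' within the current maturation period and bookkeeping accumulators
#' (material delivered to the ER, decayed material, the contents flushed at
#' the last shift, and the count of negative-overshoot clamps).
#'
#' @param species A [golgi_species()] table.
#' @param params A [golgi_parameters()] object.
#' @param init `"uniform"` fills every cisterna with `C_init` (a mature
#'   stack of identical cisternae); `"denovo"` fills only cisterna 1,
#'   letting the stack grow by maturation as it would from a single newborn
#'   cisterna.  Cisternae with zero t-SNARE neither emit nor receive
#'   vesicles, so the empty positions of a de-novo stack are inert until
#'   the conveyor reaches them.
#'
#' @return A list of class `"golgi_state"` with elements `C` (matrix,
#'   species x cisterna, cis to trans), `t_in_period`, `n_shifts`,
#'   `er_accumulated`, `decayed_accumulated`, `flushed_last`, `clamp_count`.
#' @export
#' @examples
#' sc <- build_scenario("single_snare")
#' st <- golgi_state(sc$species, sc$params)
#' dim(st$C)
golgi_state <- function(species, params, init = c("uniform", "denovo")) {
  init <- match.arg(init)
  validate_config(species, params)
  S <- nrow(species)
  N <- params$n_cisternae
  C <- matrix(0, S, N, dimnames = list(species$name, NULL))
  if (init == "uniform") C[] <- species$C_init else C[, 1] <- species$C_init
  zero <- setNames(numeric(S), species$name)
  structure(
    list(
      C = C, t_in_period = 0, n_shifts = 0L,
      er_accumulated = zero, decayed_accumulated = zero,
      flushed_last = zero, clamp_count = 0L
    ),
    class = "golgi_state"
  )
}

# S x N matrix of vesicular concentrations for every donor cisterna.
# "all": one shared site pool per vesicle. "by_class": each SNARE species
# saturates its own sites independently while passive cargo shares a pool,
# the regime in which SNARE flux is computed independently of enzyme load.
vesicle_matrix <- function(C, species, params) {
  S <- nrow(C)
  v <- matrix(0, S, ncol(C), dimnames = dimnames(C))
  n <- params$n_sites
  if (params$site_sharing == "all") {
    denom <- 1 + colSums(C / species$K)
    v <- n * (C / species$K) / rep(denom, each = S)
  } else {
    cargo <- species$role == "passive_cargo"
    for (s in which(!cargo)) {
      v[s, ] <- n * C[s, ] / (species$K[s] + C[s, ])
    }
    if (any(cargo)) {
      Cc <- C[cargo, , drop = FALSE]
      denom <- 1 + colSums(Cc / species$K[cargo])
      v[cargo, ] <- n * (Cc / species$K[cargo]) / rep(denom, each = sum(cargo))
    }
  }
  v
}

# Normalized fusion weights for every donor at once.
#
# Affinity of stack target j for a vesicle from donor i is
#   A[i, j] = v_alpha(i) * T_alpha(j) + v_beta(i) * T_beta(j);
# the ER slot uses the ER v-SNARE (or, in single-pair scenarios without a
# dedicated one, the Golgi v-SNAREs) against the fixed T_ER.
#
# Local topology: each donor has three compartment slots, cis-face / self /
# trans-face.  A face with no neighbour falls back to the donor itself
# (closed end) or to the ER zeroth cisterna (open cis end with ER access),
# so the flat zero-loss profile is an exact fixed point of the flux.
# Returns W (N x N, self multiplicity folded into the diagonal) and w_er.
weight_components <- function(C, v, species, params, include_er = TRUE) {
  N <- ncol(C)
  roles <- species$role
  A <- matrix(0, N, N)
  ia_t <- which(roles == "t_snare_alpha"); ia_v <- which(roles == "v_snare_alpha")
  ib_t <- which(roles == "t_snare_beta"); ib_v <- which(roles == "v_snare_beta")
  if (length(ia_t) && length(ia_v)) A <- A + outer(v[ia_v, ], C[ia_t, ])
  if (length(ib_t) && length(ib_v)) A <- A + outer(v[ib_v, ], C[ib_t, ])
  ier <- which(roles == "er_v_snare")
  v_er <- if (length(ier)) {
    v[ier, ]
  } else {
    iv <- c(ia_v, ib_v)
    if (length(iv)) colSums(v[iv, , drop = FALSE]) else numeric(N)
  }
  e <- v_er * params$T_ER
  er_allowed <- if (!include_er) rep(FALSE, N) else switch(params$er_access,
    none = rep(FALSE, N),
    first_cisterna_only = c(TRUE, rep(FALSE, N - 1)),
    all_cisternae = rep(TRUE, N)
  )
  W <- matrix(0, N, N)
  w_er <- numeric(N)
  for (i in seq_len(N)) {
    if (params$topology == "local") {
      targets <- max(1L, i - 1L):min(N, i + 1L)
      aff <- A[i, targets]
      extra_self <- 0
      er_aff <- 0
      if (i == 1L) {
        if (er_allowed[1L]) er_aff <- e[1L] else extra_self <- A[i, i]
      } else if (er_allowed[i]) {
        er_aff <- e[i]
      }
      if (i == N) extra_self <- extra_self + A[i, i]
      den <- sum(aff) + extra_self + er_aff
      if (den > 0) {
        W[i, targets] <- aff / den
        W[i, i] <- W[i, i] + extra_self / den
        w_er[i] <- er_aff / den
      }
    } else {
      er_aff <- if (er_allowed[i]) e[i] else 0
      den <- sum(A[i, ]) + er_aff
      if (den > 0) {
        W[i, ] <- A[i, ] / den
        w_er[i] <- er_aff / den
      }
    }
  }
  list(W = W, w_er = w_er)
}

#' Fusion weights of one donor cisterna
#'
#' The probability for a vesicle budded from `donor` to fuse with each
#' allowed target compartment.  The unnormalized affinity of stack target
#' `j` is the sum of cognate SNARE products
#' `v_alpha(donor) * T_alpha(j) + v_beta(donor) * T_beta(j)`; the ER target
#' (when this donor may reach it) contributes `v_er(donor) * T_ER`.
#' Weights are normalized to sum to one over the allowed-target set;
#' if every affinity is zero (e.g. no t-SNARE anywhere in reach) all
#' weights are zero and the donor's vesicles produce no transport.
#' Fusion with the donor itself is allowed but carries zero net flux.
#'
#' @param donor Cisterna index of the emitting compartment.
#' @param state A [golgi_state()].
#' @param species,params The scenario configuration.
#' @param cargo With `er_cargo_only` configurations, `TRUE` (default)
#'   returns the weights governing passive-cargo transport (ER target
#'   included) and `FALSE` the stack-internal weights governing the SNARE
#'   subsystem.  Ignored otherwise.
#' @return A list of class `"fusion_weights"`: `donor`, `w` (numeric of
#'   length `n_cisternae`, the weight of each stack target, self
#'   multiplicity included), and `w_er` (weight of the ER target).
#' @export
#' @examples
#' sc <- build_scenario("single_snare")
#' st <- golgi_state(sc$species, sc$params)
#' fusion_weights(2, st, sc$species, sc$params)
fusion_weights <- function(donor, state, species, params, cargo = TRUE) {
  stopifnot(donor >= 1, donor <= params$n_cisternae)
  v <- vesicle_matrix(state$C, species, params)
  include_er <- !(params$er_cargo_only && !cargo)
  wc <- weight_components(state$C, v, species, params,
    include_er = include_er)
  structure(
    list(donor = donor, w = wc$W[donor, ], w_er = wc$w_er[donor]),
    class = "fusion_weights"
  )
}

#' @export
print.fusion_weights <- function(x, ...) {
  cat("Fusion weights of donor", x$donor, "\n")
  w <- setNames(x$w, paste0("cisterna_", seq_along(x$w)))
  print(c(w, ER = x$w_er), ...)
  invisible(x)
}

#' Net concentration rate of change for every species and cisterna
#'
#' Assembles the kinetic right-hand side between shift events: first-order
#' loss, outgoing vesicular transport (the loaded vesicle concentration
#' times the total weight of non-self targets) and incoming transport from
#' every donor whose allowed-target set contains the cisterna.  The ER is a
#' target, never a donor; its uptake rate is reported as an attribute.
#'
#' @param state A [golgi_state()].
#' @param params,species The scenario configuration.
#' @return Matrix of `dC/dt` (species x cisterna) with attributes
#'   `er_rate` and `decay_rate` (per-species totals, used by the
#'   accumulators of [euler_step()]).
#' @export
#' @examples
#' sc <- build_scenario("single_snare")
#' st <- golgi_state(sc$species, sc$params)
#' rates <- flux_derivatives(st, sc$params, sc$species)
#' range(rates)
flux_derivatives <- function(state, params, species) {
  C <- state$C
  S <- nrow(C)
  v <- vesicle_matrix(C, species, params)
  split_er <- params$er_cargo_only && params$er_access != "none"
  wc <- weight_components(C, v, species, params)
  transport <- function(vrows, comp) {
    W0 <- comp$W
    diag(W0) <- 0
    outfrac <- rowSums(W0) + comp$w_er
    list(
      d = -params$omega * vrows * rep(outfrac, each = nrow(vrows)) +
        params$omega * (vrows %*% W0),
      er = params$omega * as.numeric(vrows %*% comp$w_er)
    )
  }
  if (split_er) {
    wc_snare <- weight_components(C, v, species, params, include_er = FALSE)
    cargo <- species$role == "passive_cargo"
    dC <- matrix(0, S, ncol(C), dimnames = dimnames(C))
    er_rate <- numeric(S)
    if (any(!cargo)) {
      tr <- transport(v[!cargo, , drop = FALSE], wc_snare)
      dC[!cargo, ] <- tr$d
    }
    if (any(cargo)) {
      tr <- transport(v[cargo, , drop = FALSE], wc)
      dC[cargo, ] <- tr$d
      er_rate[cargo] <- tr$er
    }
    dC <- dC - species$kappa * C
  } else {
    tr <- transport(v, wc)
    dC <- -species$kappa * C + tr$d
    er_rate <- tr$er
  }
  structure(dC,
    er_rate = setNames(er_rate, species$name),
    decay_rate = setNames(rowSums(species$kappa * C), species$name)
  )
}

#' Advance the state by one explicit Euler step
#'
#' `C <- C + dt * flux_derivatives(...)`.  Any negative entry produced by
#' overshoot is clamped to zero and counted in `clamp_count`; persistent
#' clamping is a sign that `dt` is too large for the transport intensity.
#'
#' @param state A [golgi_state()].
#' @param params,species The scenario configuration.
#' @param dt Step size; defaults to `params$dt`.
#' @param warn_clamp Emit a warning when clamping occurs (default `TRUE`;
#'   the period integrator counts silently and reports once).
#' @return The updated state.
#' @export
euler_step <- function(state, params, species, dt = params$dt,
                       warn_clamp = TRUE) {
  stopifnot(dt > 0)
  d <- flux_derivatives(state, params, species)
  d_mat <- d
  attributes(d_mat) <- attributes(d)[c("dim", "dimnames")]
  Cn <- state$C + dt * d_mat
  neg <- Cn < 0
  if (any(neg)) {
    if (warn_clamp) {
      warning(sum(neg), " negative concentration(s) clamped to zero; ",
        "consider a smaller dt", call. = FALSE)
    }
    Cn[neg] <- 0
    state$clamp_count <- state$clamp_count + sum(neg)
  }
  state$C <- Cn
  state$t_in_period <- state$t_in_period + dt
  state$er_accumulated <- state$er_accumulated + dt * attr(d, "er_rate")
  state$decayed_accumulated <-
    state$decayed_accumulated + dt * attr(d, "decay_rate")
  state
}

#' Apply one cisternal maturation (shift) event
#'
#' Every cisterna advances one position towards the trans face: the
#' contents of the trans-most cisterna are recorded as flushed output and
#' removed, and a newborn cisterna with the species' `C_init` is inserted
#' at the cis face.  The within-period clock resets.
#'
#' @param state A [golgi_state()].
#' @param species A [golgi_species()] table (provides `C_init`).
#' @return The shifted state; the removed contents are in
#'   `state$flushed_last`.
#' @export
#' @examples
#' sc <- build_scenario("single_snare")
#' st <- golgi_state(sc$species, sc$params)
#' st <- maturation_shift(st, sc$species)
#' st$n_shifts
maturation_shift <- function(state, species) {
  N <- ncol(state$C)
  state$flushed_last <- setNames(state$C[, N], species$name)
  state$C <- cbind(species$C_init, state$C[, -N, drop = FALSE])
  rownames(state$C) <- species$name
  state$n_shifts <- state$n_shifts + 1L
  state$t_in_period <- 0
  state
}

#' @export
print.golgi_state <- function(x, ...) {
  cat(sprintf(
    "Golgi state: %d species x %d cisternae, %d shift(s), phase %.4g\n",
    nrow(x$C), ncol(x$C), x$n_shifts, x$t_in_period))
  print(signif(x$C, 4))
  invisible(x)
}
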