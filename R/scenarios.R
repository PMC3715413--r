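#' Names of the built-in scenario presets
#'
#' @return Character vector of the preset names accepted by
#'   [build_scenario()].
#' @export
#' @examples
#' list_scenarios()
list_scenarios <- function() {
  c(
    "single_snare", "single_snare_loss_only", "single_snare_transport_only",
    "enzymes_open", "enzymes_closed",
    "full_mammalian", "unrestricted_yeast", "long_stack"
  )
}

#' Build a scenario preset
#'
#' Returns a fully populated and validated configuration for one of the
#' shipped study conditions.  All presets use the natural units of the
#' model: concentrations in units of the newborn-cisterna concentration
#' (`C_init = 1`), time in maturation periods (`period = 1`), and
#' `n_sites = 1` (only the product `omega * n_sites` is identifiable).
#'
#' \describe{
#'   \item{`single_snare`}{One cognate SNARE pair in a closed 8-cisterna
#'     stack.  The t-SNARE decays (`kappa = 0.2`) and is transported
#'     (`omega = 2`): both the loss seed and its vesicular
#'     self-enhancement act, giving the steepened cis-to-trans gradient.}
#'   \item{`single_snare_loss_only`}{Same, with `omega = 0`: the pure
#'     conveyor-decay profile `exp(-kappa * i)`.}
#'   \item{`single_snare_transport_only`}{Same, with `kappa = 0`: transport
#'     alone, which maintains a flat profile — no gradient without loss.}
#'   \item{`enzymes_open`}{A single SNARE pair (`kappa = 0.4` on the
#'     t-SNARE, `omega = 10`) plus three passive enzymes with the
#'     published affinities `K = 1.4, 2.5, 5` (cis, medial, trans), all
#'     species competing for the same vesicular sites.  Open boundary:
#'     the ER is a zeroth cisterna with fixed t-SNARE `T_ER = 0.7`
#'     reachable from donor 1.  Produces strictly ordered cis / medial /
#'     trans enzyme peaks, the strongest binder peaking in cisterna 1 and
#'     the weakest in the penultimate cisterna, with ER-recycled
#'     fractions ordered by binding strength.}
#'   \item{`enzymes_closed`}{The same species with no ER escape, at a
#'     gentler transport coefficient (`omega = 4`; without the ER drain
#'     the SNARE subsystem is dynamically unstable at the open preset's
#'     flux): enzyme segregation is lost, all three enzymes peak together
#'     on the trans side, and total abundance orders by binding
#'     strength.}
#'   \item{`full_mammalian`}{The eight-species two-pair model: alpha and
#'     beta t/v-SNAREs, the ER v-SNARE and the three enzymes, with the
#'     published dissociation constants (ER 0.2; alpha t and v 0.4; beta t
#'     1; beta v 5; enzymes 1.4, 2.5, 5), `T_ER = 0.7`, a small decay on
#'     the beta t-SNARE only, and ER access from every cisterna.}
#'   \item{`unrestricted_yeast`}{The `full_mammalian` configuration with
#'     the nearest-neighbour fusion restriction removed (non-stacked
#'     Golgi): vesicles reach any cisterna and the ER.  At this flux the
#'     unrestricted system settles on an oscillatory attractor rather
#'     than a fixed periodic state; read its time-averaged profiles
#'     (`average_periods` in [run_to_steady_state()]).  Enzyme peaks
#'     shift towards younger cisternae and segregation is poor.}
#'   \item{`long_stack`}{A single SNARE pair in a closed 30-cisterna stack
#'     with weak loading (`K = 20`, so concentrations stay well below `K`
#'     and loading is effectively linear), used to probe the asymptotic
#'     exponential gradient against [solve_exponent()].  Defaults give
#'     `decay_group = 0.2`, `transport_group = 1`, inside the regime
#'     where the exponential steady state is dynamically stable.}
#' }
#'
#' @param name One of [list_scenarios()].
#' @return A list of class `"golgi_scenario"` with elements `name`,
#'   `species` ([golgi_species()]) and `params` ([golgi_parameters()]),
#'   already validated.
#' @export
#' @examples
#' sc <- build_scenario("full_mammalian")
#' sc$species
#' sc$params$T_ER
build_scenario <- function(name) {
  if (!is.character(name) || length(name) != 1 ||
      !(name %in% list_scenarios())) {
    stop("unknown scenario ", deparse(substitute(name)),
      "; valid presets: ", paste(list_scenarios(), collapse = ", "),
      call. = FALSE)
  }

  pair <- function(kappa_t = 0.2, K = 1) {
    golgi_species(
      name = c("alpha_t", "alpha_v"),
      role = c("t_snare_alpha", "v_snare_alpha"),
      K = K, kappa = c(kappa_t, 0), C_init = 1
    )
  }
  # the enzyme scenarios use a stronger seed loss than the bare SNARE
  # presets: the competition mechanism needs a firmly established gradient
  enzyme_pair <- function() pair(kappa_t = 0.4)
  enzymes <- golgi_species(
    name = c("enz_cis", "enz_med", "enz_trans"),
    role = "passive_cargo",
    K = c(1.4, 2.5, 5), kappa = 0, C_init = 1
  )

  cfg <- switch(name,
    single_snare = list(
      species = pair(),
      params = golgi_parameters(omega = 2, site_sharing = "by_class")
    ),
    single_snare_loss_only = list(
      species = pair(),
      params = golgi_parameters(omega = 0, site_sharing = "by_class")
    ),
    single_snare_transport_only = list(
      species = pair(kappa_t = 0),
      params = golgi_parameters(omega = 2, site_sharing = "by_class")
    ),
    enzymes_open = list(
      species = rbind_species(enzyme_pair(), enzymes),
      params = golgi_parameters(
        omega = 10, T_ER = 0.7, boundary = "open",
        er_access = "first_cisterna_only", site_sharing = "all",
        max_periods = 800L
      )
    ),
    enzymes_closed = list(
      species = rbind_species(enzyme_pair(), enzymes),
      params = golgi_parameters(omega = 4, site_sharing = "all")
    ),
    full_mammalian = list(
      species = full_species(),
      params = golgi_parameters(
        omega = 10, T_ER = 0.7, boundary = "open",
        er_access = "all_cisternae", site_sharing = "all"
      )
    ),
    unrestricted_yeast = list(
      species = full_species(),
      params = golgi_parameters(
        omega = 10, T_ER = 0.7, boundary = "open",
        er_access = "all_cisternae", site_sharing = "all",
        topology = "unrestricted", max_periods = 300L
      )
    ),
    long_stack = list(
      species = golgi_species(
        name = c("alpha_t", "alpha_v"),
        role = c("t_snare_alpha", "v_snare_alpha"),
        K = 20, kappa = 0.2, C_init = 1
      ),
      params = golgi_parameters(
        n_cisternae = 30, omega = 20, site_sharing = "by_class"
      )
    )
  )
  validate_config(cfg$species, cfg$params)
  structure(c(list(name = name), cfg), class = "golgi_scenario")
}

full_species <- function(kappa_beta_t = 0.1) {
  golgi_species(
    name = c("er_v", "alpha_t", "alpha_v", "beta_t", "beta_v",
             "enz_cis", "enz_med", "enz_trans"),
    role = c("er_v_snare", "t_snare_alpha", "v_snare_alpha",
             "t_snare_beta", "v_snare_beta",
             "passive_cargo", "passive_cargo", "passive_cargo"),
    K = c(0.2, 0.4, 0.4, 1, 5, 1.4, 2.5, 5),
    kappa = c(0, 0, 0, kappa_beta_t, 0, 0, 0, 0),
    C_init = 1
  )
}

rbind_species <- function(...) {
  sp <- do.call(rbind, lapply(list(...), as.data.frame))
  class(sp) <- c("golgi_species", "data.frame")
  assert_species(sp)
  sp
}

#' @export
print.golgi_scenario <- function(x, ...) {
  cat("Golgi scenario preset:", x$name, "\n\n")
  print(x$species)
  cat("\n")
  print(x$params)
  invisible(x)
}
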