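#' Model parameters for a Golgi stack simulation
#'
#' Collects the stack geometry, transport intensity, boundary handling and
#' integrator settings.  Concentrations are measured in units of the
#' newborn-cisterna concentration and time in units of the maturation
#' period, so `period = 1` in every preset.
#'
#' The single coefficient `omega` lumps the budding rate, the fusion rate
#' constant, the compartment area and the vesicle-to-cisterna dilution
#' factor: at the steady state of the vesicle population these constants
#' enter every flux only as a product, so they are not separately
#' identifiable.  Likewise `n_sites` multiplies every vesicular
#' concentration and, because fusion weights are normalized, only the
#' product `omega * n_sites` matters; presets keep `n_sites = 1`.
#'
#' @param n_cisternae Stack size `N` (cis index 1 to trans index `N`).
#' @param period Maturation period `T`, the time between cisternal shifts.
#' @param omega Dimensionless vesicular transport coefficient (`>= 0`).
#' @param n_sites Concentration of cargo binding sites per vesicle.
#' @param T_ER Fixed t-SNARE concentration of the ER ("zeroth cisterna");
#'   only relevant when the boundary is open.
#' @param topology `"local"` restricts a vesicle to its donor and the two
#'   adjacent cisternae; `"unrestricted"` lets it reach every cisterna.
#' @param boundary `"open"` lets vesicles leave the Golgi for the ER,
#'   `"closed"` confines them to the stack.
#' @param er_access Which donors may fuse with the ER:
#'   `"first_cisterna_only"` (the ER acts as the zeroth cisterna reachable
#'   from donor 1), `"all_cisternae"` (the expansive ER neighbours the whole
#'   stack), or `"none"` (required when the boundary is closed).
#' @param site_sharing `"all"`: every species competes for one shared pool
#'   of vesicular sites.  `"by_class"`: each SNARE loads by its own
#'   single-species mass action while passive cargo species share one pool —
#'   the regime in which the vesicle flux is computed independently of the
#'   enzyme load.
#' @param er_cargo_only When `TRUE`, only passive cargo (enzymes) is
#'   delivered to the ER: the SNARE subsystem evolves with stack-internal
#'   fusion weights, as in the enzyme-sorting scenarios where the vesicle
#'   flux is prescribed by an autonomous SNARE gradient and the open
#'   boundary acts on the enzymes riding those vesicles.  With the default
#'   `FALSE`, every species in an ER-bound vesicle is delivered to the ER.
#' @param dt Euler time step, must be smaller than `period / 100`.
#' @param tol Steady-state tolerance: sup-norm difference between
#'   consecutive pre-shift snapshots.
#' @param max_periods Iteration cap for steady-state detection.
#'
#' @return A list of class `"golgi_parameters"`.
#' @seealso [golgi_species()], [validate_config()], [run_to_steady_state()]
#' @export
#' @examples
#' golgi_parameters(n_cisternae = 8, omega = 2)
golgi_parameters <- function(n_cisternae = 8L,
                             period = 1,
                             omega = 2,
                             n_sites = 1,
                             T_ER = 0,
                             topology = c("local", "unrestricted"),
                             boundary = c("closed", "open"),
                             er_access = c("none", "first_cisterna_only",
                                           "all_cisternae"),
                             site_sharing = c("all", "by_class"),
                             er_cargo_only = FALSE,
                             dt = 1e-3,
                             tol = 1e-8,
                             max_periods = 500L) {
  p <- list(
    n_cisternae = as.integer(n_cisternae),
    period = as.numeric(period),
    omega = as.numeric(omega),
    n_sites = as.numeric(n_sites),
    T_ER = as.numeric(T_ER),
    topology = match.arg(topology),
    boundary = match.arg(boundary),
    er_access = match.arg(er_access),
    site_sharing = match.arg(site_sharing),
    er_cargo_only = isTRUE(er_cargo_only),
    dt = as.numeric(dt),
    tol = as.numeric(tol),
    max_periods = as.integer(max_periods)
  )
  class(p) <- "golgi_parameters"
  assert_parameters(p)
  p
}

assert_parameters <- function(p) {
  stopifnot(inherits(p, "golgi_parameters"))
  if (p$n_cisternae < 2L) stop("n_cisternae must be >= 2", call. = FALSE)
  if (!is.finite(p$period) || p$period <= 0) {
    stop("period must be positive", call. = FALSE)
  }
  if (!is.finite(p$omega) || p$omega < 0) {
    stop("omega must be nonnegative", call. = FALSE)
  }
  if (!is.finite(p$n_sites) || p$n_sites <= 0) {
    stop("n_sites must be positive", call. = FALSE)
  }
  if (!is.finite(p$T_ER) || p$T_ER < 0) {
    stop("T_ER must be nonnegative", call. = FALSE)
  }
  if (!is.finite(p$dt) || p$dt <= 0 || p$dt >= p$period / 100) {
    stop("dt must satisfy 0 < dt < period/100 (got dt = ", p$dt,
      ", period = ", p$period, ")", call. = FALSE)
  }
  if (!is.finite(p$tol) || p$tol <= 0) stop("tol must be positive", call. = FALSE)
  if (p$max_periods < 1L) stop("max_periods must be >= 1", call. = FALSE)
  if (p$boundary == "closed" && p$er_access != "none") {
    stop("a closed boundary requires er_access = \"none\" (got \"",
      p$er_access, "\")", call. = FALSE)
  }
  if (p$boundary == "open" && p$er_access == "none") {
    stop("an open boundary requires er_access \"first_cisterna_only\" or ",
      "\"all_cisternae\"", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.golgi_parameters <- function(x, ...) {
  cat("Golgi model parameters\n")
  cat(sprintf("  stack: N = %d cisternae, period = %g\n",
    x$n_cisternae, x$period))
  cat(sprintf("  transport: omega = %g, n_sites = %g, topology = %s\n",
    x$omega, x$n_sites, x$topology))
  cat(sprintf("  boundary: %s (er_access = %s, T_ER = %g)\n",
    x$boundary, x$er_access, x$T_ER))
  cat(sprintf("  loading: site_sharing = %s\n", x$site_sharing))
  cat(sprintf("  integrator: dt = %g, tol = %g, max_periods = %d\n",
    x$dt, x$tol, x$max_periods))
  invisible(x)
}
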