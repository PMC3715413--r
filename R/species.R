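#' Define the transported species of a scenario
#'
#' Builds the species table of a Golgi transport model: one row per molecule
#' class (a SNARE or a resident enzyme).  All concentrations are measured in
#' units of the newborn-cisterna concentration, so a typical species has
#' `C_init = 1`.
#'
#' @param name Character vector of unique short identifiers
#'   (e.g. `"alpha_t"`, `"enz_cis"`).
#' @param role Character vector of roles, each one of [golgi_roles()].
#'   Fusion weights are built from the cognate pairs
#'   (`v_snare_alpha` with `t_snare_alpha`, `v_snare_beta` with
#'   `t_snare_beta`) and from `er_v_snare` against the fixed ER t-SNARE;
#'   `passive_cargo` never enters a fusion weight.
#' @param K Dissociation constant for the vesicular binding sites, in units
#'   of the reference concentration.  Lower `K` means a stronger competitor
#'   for vesicle space.
#' @param kappa First-order loss rate per maturation period (degradation,
#'   mis-targeting, inactivation).  The lost material is removed from the
#'   system, not routed anywhere.
#' @param C_init Concentration loaded into each newborn cisterna.
#'
#' @return A `data.frame` of class `"golgi_species"` with columns
#'   `name`, `role`, `K`, `kappa`, `C_init`.
#' @seealso [golgi_parameters()], [build_scenario()], [validate_config()]
#' @export
#' @examples
#' golgi_species(
#'   name  = c("alpha_t", "alpha_v"),
#'   role  = c("t_snare_alpha", "v_snare_alpha"),
#'   K     = c(1, 1),
#'   kappa = c(0.2, 0)
#' )
golgi_species <- function(name, role, K, kappa = 0, C_init = 1) {
  n <- length(name)
  sp <- data.frame(
    name = as.character(name),
    role = as.character(role),
    K = as.numeric(rep_len(K, n)),
    kappa = as.numeric(rep_len(kappa, n)),
    C_init = as.numeric(rep_len(C_init, n)),
    stringsAsFactors = FALSE
  )
  class(sp) <- c("golgi_species", "data.frame")
  assert_species(sp)
  sp
}

assert_species <- function(sp) {
  if (!all(c("name", "role", "K", "kappa", "C_init") %in% names(sp))) {
    stop("species table must have columns name, role, K, kappa, C_init",
      call. = FALSE)
  }
  if (anyDuplicated(sp$name)) {
    stop("duplicate species names: ",
      paste(unique(sp$name[duplicated(sp$name)]), collapse = ", "),
      call. = FALSE)
  }
  bad <- setdiff(sp$role, .golgi_roles)
  if (length(bad)) {
    stop("unknown species role(s): ", paste(bad, collapse = ", "),
      "; valid roles: ", paste(.golgi_roles, collapse = ", "), call. = FALSE)
  }
  dup_role <- sp$role[sp$role != "passive_cargo"]
  if (anyDuplicated(dup_role)) {
    stop("each SNARE role may appear at most once; duplicated: ",
      paste(unique(dup_role[duplicated(dup_role)]), collapse = ", "),
      call. = FALSE)
  }
  if (any(!is.finite(sp$K)) || any(sp$K <= 0)) {
    stop("dissociation constants K must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(sp$kappa)) || any(sp$kappa < 0)) {
    stop("loss rates kappa must be nonnegative and finite", call. = FALSE)
  }
  if (any(!is.finite(sp$C_init)) || any(sp$C_init < 0)) {
    stop("initial concentrations C_init must be nonnegative and finite",
      call. = FALSE)
  }
  invisible(sp)
}

# integer role codes used by the compiled integrator (0-based)
role_codes <- function(sp) match(sp$role, .golgi_roles) - 1L

#' @export
print.golgi_species <- function(x, ...) {
  cat("Golgi species table (", nrow(x), " species)\n", sep = "")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
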