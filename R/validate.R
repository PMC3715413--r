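#' Validate a species/parameters configuration
#'
#' Enforces every structural invariant of a scenario before it is run:
#' positive dissociation constants, nonnegative rates and concentrations, a
#' consistent boundary/ER-access combination, an integrator step compatible
#' with the period, and — whenever vesicular transport is active
#' (`omega > 0`) — the presence of at least one t-SNARE and one v-SNARE
#' role, since fusion weights are built from cognate SNARE products.
#'
#' @param species A [golgi_species()] table.
#' @param params A [golgi_parameters()] object.
#' @return Invisibly, `list(species = species, params = params)`; an error
#'   describing the first violated invariant otherwise.
#' @export
#' @examples
#' sc <- build_scenario("single_snare")
#' validate_config(sc$species, sc$params)
validate_config <- function(species, params) {
  assert_species(species)
  assert_parameters(params)
  roles <- species$role
  if (params$omega > 0) {
    has_t <- any(roles %in% c("t_snare_alpha", "t_snare_beta"))
    has_v <- any(roles %in% c("v_snare_alpha", "v_snare_beta", "er_v_snare"))
    if (!has_t || !has_v) {
      stop("omega > 0 requires at least one t-SNARE and one v-SNARE role ",
        "to form fusion weights; found roles: ",
        paste(roles, collapse = ", "), call. = FALSE)
    }
    # a pair only fuses when both halves exist; warn on widowed halves
    for (pair in list(c("t_snare_alpha", "v_snare_alpha"),
                      c("t_snare_beta", "v_snare_beta"))) {
      n_half <- sum(roles %in% pair)
      if (n_half == 1L) {
        warning("SNARE role ", intersect(pair, roles),
          " has no cognate partner and contributes no fusion weight",
          call. = FALSE)
      }
    }
  }
  if (params$boundary == "open" && params$T_ER <= 0) {
    stop("an open boundary requires T_ER > 0 so that vesicles can fuse ",
      "with the ER", call. = FALSE)
  }
  invisible(list(species = species, params = params))
}
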