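#' Read a scenario configuration from a YAML file
#'
#' The file has two top-level keys: `parameters`, a mapping whose keys are
#' exactly the fields of [golgi_parameters()], and `species`, a sequence of
#' mappings with the fields of [golgi_species()] (`kappa` and `C_init` may
#' be omitted and default to 0 and 1).  Unknown keys at either level are
#' rejected.  The loaded configuration is validated before it is returned.
#'
#' @param path Path to the YAML file.
#' @return A list of class `"golgi_scenario"` with `name` (the file name
#'   without extension), `species` and `params`.
#' @seealso [write_config()], [build_scenario()]
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  top_bad <- setdiff(names(raw), c("name", "parameters", "species"))
  if (length(top_bad)) {
    stop("unknown top-level config key(s): ", paste(top_bad, collapse = ", "),
      call. = FALSE)
  }
  if (is.null(raw$parameters) || is.null(raw$species)) {
    stop("config must contain 'parameters' and 'species'", call. = FALSE)
  }
  par_fields <- names(formals(golgi_parameters))
  bad <- setdiff(names(raw$parameters), par_fields)
  if (length(bad)) {
    stop("unknown parameter key(s): ", paste(bad, collapse = ", "),
      "; valid keys: ", paste(par_fields, collapse = ", "), call. = FALSE)
  }
  params <- do.call(golgi_parameters, raw$parameters)
  sp_fields <- c("name", "role", "K", "kappa", "C_init")
  rows <- lapply(raw$species, function(s) {
    bad <- setdiff(names(s), sp_fields)
    if (length(bad)) {
      stop("unknown species key(s): ", paste(bad, collapse = ", "),
        call. = FALSE)
    }
    if (is.null(s$name) || is.null(s$role) || is.null(s$K)) {
      stop("each species needs at least name, role and K", call. = FALSE)
    }
    data.frame(
      name = s$name, role = s$role, K = as.numeric(s$K),
      kappa = as.numeric(s$kappa %||% 0),
      C_init = as.numeric(s$C_init %||% 1),
      stringsAsFactors = FALSE
    )
  })
  species <- do.call(rbind, rows)
  class(species) <- c("golgi_species", "data.frame")
  assert_species(species)
  validate_config(species, params)
  nm <- raw$name %||% sub("\\.[^.]*$", "", basename(path))
  structure(list(name = nm, species = species, params = params),
    class = "golgi_scenario")
}

#' Write a scenario configuration to a YAML file
#'
#' Inverse of [read_config()]: the written file reloads to an identical
#' configuration (numeric values are emitted with 15 significant digits).
#'
#' @param config A `"golgi_scenario"` (from [build_scenario()] or
#'   [read_config()]) or a `list(species = , params = )`.
#' @param path Destination file.
#' @return Invisibly, `path`.
#' @export
#' @examples
#' path <- tempfile(fileext = ".yaml")
#' write_config(build_scenario("single_snare"), path)
#' identical(read_config(path)$params, build_scenario("single_snare")$params)
write_config <- function(config, path) {
  sp <- config$species
  out <- list(
    name = config$name %||% "custom",
    parameters = unclass(config$params),
    species = lapply(seq_len(nrow(sp)), function(i) {
      list(name = sp$name[i], role = sp$role[i], K = sp$K[i],
        kappa = sp$kappa[i], C_init = sp$C_init[i])
    })
  )
  writeLines(yaml::as.yaml(out, precision = 15), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
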