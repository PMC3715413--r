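#' Write converged profiles as a tidy CSV table
#'
#' One row per species and cisterna, in deterministic order (species in
#' table order, cisterna ascending), with a per-species normalized column
#' (`concentration / max(concentration)`, the convention used to plot
#' enzyme distributions).  Values are printed with 12 significant digits,
#' so re-reading the file reproduces the matrix to that precision.
#'
#' @param result A `"golgi_result"` from [run_to_steady_state()].
#' @param path Destination CSV file.
#' @param scenario Scenario label for the first column.
#' @return Invisibly, `path`.
#' @seealso [read_profiles()], [summarize_run()]
#' @export
write_profiles <- function(result, path, scenario = "custom") {
  prof <- result$profiles
  sp <- rownames(prof)
  N <- ncol(prof)
  norm <- prof / apply(prof, 1, function(r) if (max(r) > 0) max(r) else 1)
  df <- data.frame(
    scenario = scenario,
    species = rep(sp, each = N),
    cisterna = rep(seq_len(N), times = length(sp)),
    concentration = sprintf("%.12g", as.vector(t(prof))),
    normalized_concentration = sprintf("%.12g", as.vector(t(norm))),
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a profiles CSV back into a species-by-cisterna matrix
#'
#' @param path A CSV written by [write_profiles()].
#' @return A numeric matrix with species as rows (in file order) and an
#'   attribute `scenario`.
#' @export
read_profiles <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("scenario", "species", "cisterna", "concentration",
    "normalized_concentration")
  if (!all(need %in% names(df))) {
    stop("not a profiles table; expected columns: ",
      paste(need, collapse = ", "), call. = FALSE)
  }
  sp <- unique(df$species)
  N <- max(df$cisterna)
  m <- matrix(NA_real_, length(sp), N, dimnames = list(sp, NULL))
  m[cbind(match(df$species, sp), df$cisterna)] <- df$concentration
  attr(m, "scenario") <- df$scenario[1]
  m
}

#' Summarize a converged run
#'
#' Derives, per species, the location and height of the concentration
#' peak, the ER-recycled fraction, and a monotonicity flag across the
#' stack (`"increasing"`, `"decreasing"`, `"unimodal"`, `"constant"` or
#' `"irregular"`, judged with a relative tolerance of `1e-6`).  All
#' summaries are recomputable from the profile table alone.
#'
#' @param result A `"golgi_result"`.
#' @param scenario Scenario label.
#' @param profiles_file Optional path of the CSV the profiles were written
#'   to, recorded for reference.
#' @return A list of class `"golgi_report"` with fields `scenario`,
#'   `parameters`, `convergence`, `species` (a data.frame of per-species
#'   summaries), `fitted_exponent` and `profiles_file`.  A non-converged
#'   result is summarized anyway and flagged.
#' @export
#' @examples
#' sc <- build_scenario("single_snare_loss_only")
#' res <- run_to_steady_state(sc$species, sc$params)
#' summarize_run(res, scenario = sc$name)$species
summarize_run <- function(result, scenario = "custom", profiles_file = NULL) {
  prof <- result$profiles
  sp <- rownames(prof)
  summ <- data.frame(
    species = sp,
    argmax = apply(prof, 1, which.max),
    peak_value = apply(prof, 1, max),
    er_fraction = as.numeric(result$er_fraction[sp]),
    monotonicity = apply(prof, 1, monotonicity_flag),
    stringsAsFactors = FALSE
  )
  rownames(summ) <- NULL
  fe <- result$fitted_exponent
  structure(
    list(
      scenario = scenario,
      parameters = unclass(result$params),
      convergence = list(
        converged = result$converged,
        n_periods_used = result$n_periods_used,
        residual = result$residual,
        clamp_count = as.integer(result$clamp_count)
      ),
      species = summ,
      fitted_exponent = if (is.null(fe)) NULL else as.list(fe),
      profiles_file = profiles_file
    ),
    class = "golgi_report"
  )
}

monotonicity_flag <- function(x, rtol = 1e-6) {
  tol <- rtol * max(abs(x), 1e-300)
  d <- diff(x)
  if (all(abs(d) <= tol)) return("constant")
  up <- d > tol
  dn <- d < -tol
  if (!any(dn)) return("increasing")
  if (!any(up)) return("decreasing")
  # unimodal: every rise precedes every fall
  if (max(which(up)) < min(which(dn))) return("unimodal")
  "irregular"
}

#' Write a run report as JSON
#'
#' @param report A `"golgi_report"` from [summarize_run()].
#' @param path Destination file.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path,
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Validate a report against the shipped JSON schema
#'
#' Structural check of a report file (or in-memory report) against the
#' schema in `inst/schema/report-schema.json`: required fields, field
#' types and enumerated values.  This is a lightweight subset of JSON
#' Schema sufficient for the report format.
#'
#' @param report A `"golgi_report"`, or the path of a JSON report file.
#' @param schema_path Schema file; defaults to the shipped schema.
#' @return `TRUE` if valid, otherwise an error listing the violations.
#' @export
validate_report <- function(report,
                            schema_path = system.file("schema",
                              "report-schema.json", package = "golgisim")) {
  if (is.character(report)) report <- jsonlite::read_json(report)
  report <- unclass(report)
  schema <- jsonlite::read_json(schema_path)
  errs <- character()
  check <- function(obj, sch, where) {
    type <- sch$type
    ok_type <- switch(type,
      object = is.list(obj) && !is.null(names(obj)) || (is.list(obj) && length(obj) == 0),
      array = is.list(obj) || (is.vector(obj) && is.null(names(obj))),
      string = is.character(obj) && length(obj) == 1,
      number = is.numeric(obj) && length(obj) == 1,
      integer = is.numeric(obj) && length(obj) == 1 &&
        (!is.finite(obj) || obj == round(obj)),
      boolean = is.logical(obj) && length(obj) == 1,
      TRUE
    )
    if (!isTRUE(ok_type)) {
      errs <<- c(errs, sprintf("%s: expected %s", where, type))
      return(invisible())
    }
    if (type == "object") {
      for (req in sch$required %||% list()) {
        if (!(req %in% names(obj)) || is.null(obj[[req]])) {
          errs <<- c(errs, sprintf("%s: missing required field '%s'", where, req))
        }
      }
      for (nm in names(sch$properties %||% list())) {
        if (!is.null(obj[[nm]])) {
          check(obj[[nm]], sch$properties[[nm]], paste0(where, ".", nm))
        }
      }
    } else if (type == "array" && !is.null(sch$items)) {
      for (k in seq_along(obj)) {
        check(obj[[k]], sch$items, sprintf("%s[%d]", where, k))
      }
    } else if (!is.null(sch$enum)) {
      if (!(obj %in% unlist(sch$enum))) {
        errs <<- c(errs, sprintf("%s: '%s' not in allowed values", where, obj))
      }
    }
  }
  # the species table serializes as an array of row objects
  if (is.data.frame(report$species)) {
    report$species <- lapply(seq_len(nrow(report$species)), function(i) {
      as.list(report$species[i, ])
    })
  }
  check(report, schema, "report")
  if (length(errs)) {
    stop("report fails schema validation:\n  ",
      paste(errs, collapse = "\n  "), call. = FALSE)
  }
  TRUE
}

#' @export
print.golgi_report <- function(x, ...) {
  cat("Run report:", x$scenario, "\n")
  cv <- x$convergence
  cat(sprintf("  %s in %d period(s), residual %.3g\n",
    if (cv$converged) "converged" else "NOT converged",
    cv$n_periods_used, cv$residual))
  print(x$species, row.names = FALSE)
  invisible(x)
}
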