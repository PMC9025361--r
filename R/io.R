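#' Read a pH monitoring dataset from CSV
#'
#' Expects a header with columns `batch_id`, `lactate_pct`, `atmosphere`,
#' `day`, `pH`. Atmosphere tokens are matched case-insensitively against
#' `Air`, `MAP1`, `MAP2`. Rows with missing or non-numeric pH, negative
#' days or unknown atmosphere tokens are reported with their row numbers.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble of observations.
#' @export
read_ph_data <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    batch_id = readr::col_character(),
    lactate_pct = readr::col_double(),
    atmosphere = readr::col_character(),
    day = readr::col_double(),
    pH = readr::col_double()
  ))
  required <- c("batch_id", "lactate_pct", "atmosphere", "day", "pH")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s is missing column(s): %s", path,
                  paste(missing_cols, collapse = ", ")))
  }
  problems <- character(0)
  report <- function(rows, what, values) {
    if (length(rows) > 0) {
      problems <<- c(problems, sprintf(
        "row %d: %s (%s)", rows, what, values
      ))
    }
  }
  bad_ph <- which(!is.finite(raw$pH))
  report(bad_ph, "missing or non-numeric pH", raw$pH[bad_ph])
  bad_day <- which(is.na(raw$day) | raw$day < 0)
  report(bad_day, "invalid storage day", raw$day[bad_day])
  bad_lact <- which(is.na(raw$lactate_pct) | raw$lactate_pct < 0)
  report(bad_lact, "invalid lactate dose", raw$lactate_pct[bad_lact])
  bad_atm <- which(!tolower(raw$atmosphere) %in% tolower(ATMOSPHERES))
  report(bad_atm, "unknown atmosphere token", raw$atmosphere[bad_atm])
  if (length(problems) > 0) {
    abort(paste0("Invalid rows in ", path, ":\n",
                 paste(" ", problems, collapse = "\n")))
  }
  raw$atmosphere <- match_atmosphere(raw$atmosphere)
  raw
}

#' Write a pH monitoring dataset to CSV
#'
#' Writes the observation columns to `path`. When the data carries a
#' generating-truth attribute (from [simulate_ph_data()]) and `truth_path`
#' is given, the truth (all parameters plus the per-batch initial pH
#' values) is written as a JSON sidecar, kept separate from the CSV so a
#' fitting pipeline reading the data never sees it.
#'
#' @param data Observation table.
#' @param path Output CSV path.
#' @param truth_path Optional path for the JSON truth sidecar.
#' @return `path`, invisibly.
#' @export
write_ph_data <- function(data, path, truth_path = NULL) {
  data <- validate_ph_data(tibble::as_tibble(data))
  readr::write_csv(data[c("batch_id", "lactate_pct", "atmosphere", "day", "pH")],
                   path)
  truth <- attr(data, "truth")
  if (!is.null(truth_path)) {
    if (is.null(truth)) abort("`truth_path` given but the data carries no truth attribute.")
    jsonlite::write_json(
      c(truth[setdiff(names(truth), "pH0")], list(pH0 = as.list(truth$pH0))),
      truth_path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' Read a generating-truth sidecar written by [write_ph_data()]
#'
#' @param path Path to the JSON sidecar.
#' @return A [ph_params()] state with per-batch `pH0` values.
#' @export
read_ph_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ph_params(
    mu_pH0 = x$mu_pH0, sigma_pH0 = x$sigma_pH0, sigma_pH = x$sigma_pH,
    lambda = x$lambda, delta_Air = x$delta_Air, delta_MAP1 = x$delta_MAP1,
    delta_MAP2 = x$delta_MAP2, n = x$n, theta = x$theta,
    pH0 = unlist(x$pH0)
  )
}

#' Write a trace to CSV (long format) with a JSON run manifest
#'
#' The CSV has columns `chain`, `iteration`, `parameter`, `value` for every
#' retained draw (including per-draw deviance as parameter `"deviance"`);
#' the manifest records the variant, configuration, seed and acceptance
#' rates.
#'
#' @param fit A [fit_ph_model()] result.
#' @param csv_path Output CSV path.
#' @param manifest_path Optional JSON manifest path.
#' @return `csv_path`, invisibly.
#' @export
write_trace <- function(fit, csv_path, manifest_path = NULL) {
  stopifnot(inherits(fit, "ph_fit"))
  long <- purrr::map_dfr(seq_along(fit$draws), function(ch) {
    d <- fit$draws[[ch]]
    tibble::tibble(
      chain = ch,
      iteration = rep(seq_len(nrow(d)), times = ncol(d) + 1),
      parameter = rep(c(colnames(d), "deviance"), each = nrow(d)),
      value = c(as.vector(d), fit$deviance[[ch]])
    )
  })
  readr::write_csv(long, csv_path)
  if (!is.null(manifest_path)) {
    jsonlite::write_json(
      list(
        variant = fit$variant$name,
        config = fit$config[c("n_chains", "burn_in", "n_iterations",
                              "thinning", "seed")],
        n_obs = fit$n_obs,
        batches = fit$batch_levels,
        acceptance = purrr::map(fit$acceptance, as.list)
      ),
      manifest_path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(csv_path)
}
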