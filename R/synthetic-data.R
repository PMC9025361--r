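#' Study design for pH monitoring
#'
#' Describes the factorial monitoring design: a number of independent
#' production batches, a set of lactate doses crossed with packaging
#' atmospheres (the "process conditions"), and common sampling days. The
#' defaults reproduce the original study: 10 batches, doses of 0 / 1 / 2 %
#' w/w, three atmospheres, and sampling at days 2, 8, 15 and 22, with one pH
#' value per (batch, condition, day) as technical replicates were averaged
#' before analysis.
#'
#' @param n_batches Number of production batches (>= 1).
#' @param lactate_doses Lactate doses in % w/w.
#' @param atmospheres Subset of `c("Air", "MAP1", "MAP2")`.
#' @param sampling_days Strictly increasing, non-negative storage days.
#' @param replicates_per_point Observations per (batch, condition, day).
#'
#' @return A list of class `ph_design`.
#' @examples
#' ph_design()
#' @export
ph_design <- function(n_batches = 10,
                      lactate_doses = c(0, 1, 2),
                      atmospheres = c("Air", "MAP1", "MAP2"),
                      sampling_days = c(2, 8, 15, 22),
                      replicates_per_point = 1) {
  atmospheres <- match_atmosphere(atmospheres)
  if (n_batches < 1 || replicates_per_point < 1) {
    abort("`n_batches` and `replicates_per_point` must be >= 1.")
  }
  if (length(sampling_days) < 1 || any(sampling_days < 0) ||
      is.unsorted(sampling_days, strictly = TRUE)) {
    abort("`sampling_days` must be strictly increasing and >= 0.")
  }
  if (length(lactate_doses) < 1 || any(lactate_doses < 0)) {
    abort("`lactate_doses` must be >= 0.")
  }
  structure(
    list(
      n_batches = as.integer(n_batches),
      lactate_doses = lactate_doses,
      atmospheres = atmospheres,
      sampling_days = sampling_days,
      replicates_per_point = as.integer(replicates_per_point)
    ),
    class = "ph_design"
  )
}

#' @export
print.ph_design <- function(x, ...) {
  cat(sprintf(
    "<ph_design> %d batches x %d conditions (%s %% w/w lactate x %s) x days %s%s\n",
    x$n_batches,
    length(x$lactate_doses) * length(x$atmospheres),
    paste(x$lactate_doses, collapse = "/"),
    paste(x$atmospheres, collapse = "/"),
    paste(x$sampling_days, collapse = ", "),
    if (x$replicates_per_point > 1)
      sprintf(" (%d replicates)", x$replicates_per_point) else ""
  ))
  invisible(x)
}

#' Simulate a pH monitoring dataset from known parameters
#'
#' Generates data with exactly the generative structure the model assumes:
#' each batch draws one initial pH from `N(mu_pH0, sigma_pH0)` shared across
#' all of its conditions, and every observation adds Gaussian measurement
#' noise `N(0, sigma_pH)` around the two-phase mean curve.
#'
#' The drawn per-batch initial pH values are attached as attribute `"truth"`
#' (a [ph_params()] state with `pH0` filled in) so that recovery experiments
#' can compare estimates against the generating latent values; use
#' [ph_truth()] to retrieve them. [write_ph_data()] stores this provenance
#' in a separate sidecar file so a fitting pipeline reading the CSV never
#' sees it.
#'
#' @param design A [ph_design()].
#' @param truth A [ph_params()] state used as generating truth.
#' @param seed Integer seed; the same (design, truth, seed) triple always
#'   yields the identical dataset.
#'
#' @return A tibble with columns `batch_id`, `lactate_pct`, `atmosphere`,
#'   `day`, `pH` (one row per observation), carrying the `"truth"`
#'   attribute.
#' @examples
#' sim <- simulate_ph_data(ph_design(), ph_params(), seed = 1)
#' nrow(sim)  # 10 batches x 9 conditions x 4 days = 360
#' @export
simulate_ph_data <- function(design = ph_design(), truth = ph_params(),
                             seed) {
  stopifnot(inherits(design, "ph_design"), inherits(truth, "ph_params"))
  if (missing(seed)) abort("`seed` is required for reproducibility.")

  grid <- tidyr::expand_grid(
    batch_id = sprintf("B%02d", seq_len(design$n_batches)),
    lactate_pct = design$lactate_doses,
    atmosphere = design$atmospheres,
    day = design$sampling_days,
    replicate = seq_len(design$replicates_per_point)
  )

  deltas <- c(truth$delta_Air, truth$delta_MAP1, truth$delta_MAP2)
  beta <- exp(truth$lambda * lactate_power(grid$lactate_pct, truth$n) +
                deltas[match(grid$atmosphere, ATMOSPHERES)])
  if (any(!is.finite(beta))) {
    abort("Generating truth yields a non-finite acidification rate for this design.")
  }

  batch_ids <- sprintf("B%02d", seq_len(design$n_batches))
  withr_seed <- function(code) { # local RNG scope without a dependency
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
    code
  }
  sim <- withr_seed({
    pH0 <- setNames(rnorm(design$n_batches, truth$mu_pH0, truth$sigma_pH0),
                    batch_ids)
    m <- pH0[match(grid$batch_id, batch_ids)] -
      beta * pmin(grid$day, truth$theta)
    list(pH0 = pH0, pH = rnorm(nrow(grid), m, truth$sigma_pH))
  })

  out <- tibble::tibble(
    batch_id = grid$batch_id,
    lactate_pct = grid$lactate_pct,
    atmosphere = grid$atmosphere,
    day = grid$day,
    pH = sim$pH
  )
  truth$pH0 <- sim$pH0
  attr(out, "truth") <- truth
  attr(out, "design") <- design
  out
}

#' Retrieve the generating truth attached to a simulated dataset
#'
#' @param data A tibble produced by [simulate_ph_data()].
#' @return The [ph_params()] generating state with per-batch `pH0` values,
#'   or `NULL` when the data carries no provenance.
#' @export
ph_truth <- function(data) {
  attr(data, "truth")
}
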