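#' Posterior(-predictive) pH kinetics with credible bands
#'
#' For every pooled posterior draw, computes the pH trajectory over a time
#' grid under a given lactate dose and atmosphere, then summarises the
#' draws pointwise in time by their median and 2.5% / 97.5% quantiles.
#'
#' Two batch modes are available: `"new_batch"` (default) draws a fresh
#' initial pH from `N(mu_pH0, sigma_pH0)` per posterior draw, so the band
#' reflects kinetic uncertainty plus between-batch variability; or
#' `"mean_batch"` uses the population mean initial pH of each draw. Setting
#' `noise = TRUE` additionally adds Gaussian measurement error
#' `N(0, sigma_pH)` per draw, widening the band to a predictive band for a
#' single measurement.
#'
#' @param fit A [fit_ph_model()] result.
#' @param lactate Lactate dose in % w/w.
#' @param atmosphere One of `"Air"`, `"MAP1"`, `"MAP2"`.
#' @param time_grid Non-negative storage days (default 0 to 22).
#' @param mode `"new_batch"` or `"mean_batch"`.
#' @param noise Add per-draw measurement noise? Default `FALSE`.
#' @param seed Integer seed for the batch/noise draws (default 1).
#'
#' @return A tibble of class `ph_band` with columns `day`, `median`,
#'   `lower`, `upper` plus metadata columns `lactate_pct`, `atmosphere`,
#'   `mode`, `noise`.
#' @export
simulate_kinetics <- function(fit, lactate, atmosphere,
                              time_grid = seq(0, 22, by = 0.5),
                              mode = c("new_batch", "mean_batch"),
                              noise = FALSE, seed = 1) {
  stopifnot(inherits(fit, "ph_fit"))
  mode <- match.arg(mode)
  atmosphere <- match_atmosphere(atmosphere)
  if (length(time_grid) == 0 || any(time_grid < 0)) {
    abort("`time_grid` must be non-empty and non-negative.")
  }
  if (length(lactate) != 1 || lactate < 0) abort("`lactate` must be a single value >= 0.")

  d <- pooled_draws(fit)
  ndraw <- nrow(d)
  delta_col <- paste0("delta_", atmosphere)
  # lactate^n per draw, with 0^n := 0 for n > 0
  Lp <- if (lactate == 0) ifelse(d[, "n"] > 0, 0, NaN) else lactate^d[, "n"]
  beta <- exp(d[, "lambda"] * Lp + d[, delta_col])
  if (any(!is.finite(beta))) {
    abort("Non-finite acidification rate for some posterior draws at this lactate dose.")
  }
  set.seed(seed)
  pH0_star <- if (mode == "new_batch") {
    rnorm(ndraw, d[, "mu_pH0"], d[, "sigma_pH0"])
  } else {
    d[, "mu_pH0"]
  }
  mt <- outer(d[, "theta"], time_grid, pmin) # ndraw x grid
  curves <- pH0_star - beta * mt
  if (noise) {
    curves <- curves + matrix(rnorm(length(curves), 0, d[, "sigma_pH"]),
                              nrow = ndraw)
  }
  qs <- apply(curves, 2, quantile, probs = c(0.025, 0.5, 0.975),
              names = FALSE)
  out <- tibble::tibble(
    day = time_grid,
    median = qs[2, ],
    lower = qs[1, ],
    upper = qs[3, ],
    lactate_pct = lactate,
    atmosphere = atmosphere,
    mode = mode,
    noise = noise
  )
  class(out) <- c("ph_band", class(out))
  out
}

#' Acidification rate as a function of lactate dose
#'
#' Evaluates the rate `beta = exp(lambda * lactate^n + delta)` at the
#' posterior point estimates over a grid of lactate doses, for one
#' atmosphere — the rate-vs-dose curve showing how lactate addition slows
#' acidification.
#'
#' @param summary A [summarize_posterior()] result.
#' @param lactate_grid Non-negative lactate doses in % w/w.
#' @param atmosphere One of `"Air"`, `"MAP1"`, `"MAP2"`.
#' @return A tibble with columns `lactate_pct`, `atmosphere`, `rate`.
#' @export
rate_curve <- function(summary, lactate_grid = seq(0, 2, by = 0.05),
                       atmosphere = "Air") {
  stopifnot(inherits(summary, "ph_summary"))
  atmosphere <- match_atmosphere(atmosphere)
  if (any(lactate_grid < 0)) abort("`lactate_grid` must be >= 0.")
  est <- setNames(summary$median, summary$parameter)
  beta <- acidification_rate(est[["lambda"]], est[["n"]],
                             est[[paste0("delta_", atmosphere)]],
                             lactate_grid)
  out <- tibble::tibble(
    lactate_pct = lactate_grid,
    atmosphere = atmosphere,
    rate = beta
  )
  class(out) <- c("ph_rate_curve", class(out))
  out
}
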