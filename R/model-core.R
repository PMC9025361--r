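#' Kinetic model parameter state
#'
#' Bundles one complete setting of the two-phase acidification model:
#' population-level parameters, the measurement noise, and (optionally) the
#' latent initial pH of each production batch. Defaults are the point
#' estimates obtained for the selected model variant on the original poultry
#' sausage study, so `ph_params()` with no arguments is a realistic truth for
#' simulation.
#'
#' The model says that within a production batch the pH starts at a
#' batch-specific initial value `pH0`, decreases linearly at rate
#' `beta = exp(lambda * lactate^n + delta_p)` (pH units/day, depending on the
#' lactate dose in % w/w and the packaging atmosphere p), and stabilises at
#' time `theta` (days), staying constant afterwards.
#'
#' @param mu_pH0 Mean initial pH across production batches (pH units).
#' @param sigma_pH0 Between-batch standard deviation of initial pH (>= 0).
#' @param sigma_pH Measurement standard deviation (>= 0, pH units).
#' @param lambda Slope of the lactate effect on the log acidification rate.
#' @param delta_Air,delta_MAP1,delta_MAP2 Additive atmosphere effects on the
#'   log acidification rate (dimensionless).
#' @param n Scale exponent applied to the lactate dose (1 gives a log-linear
#'   first-order effect).
#' @param theta Stabilisation time in days (> 0).
#' @param pH0 Optional numeric vector of latent per-batch initial pH values,
#'   named by batch id.
#'
#' @return A list of class `ph_params`.
#' @examples
#' truth <- ph_params()
#' acidification_rate(truth$lambda, truth$n, truth$delta_MAP2, lactate = 0)
#' @export
ph_params <- function(mu_pH0 = 6.49, sigma_pH0 = 0.10, sigma_pH = 0.15,
                      lambda = -0.095, delta_Air = -2.430,
                      delta_MAP1 = -2.487, delta_MAP2 = -2.339,
                      n = 1, theta = 12.9, pH0 = NULL) {
  stopifnot(sigma_pH0 >= 0, sigma_pH >= 0, theta > 0)
  structure(
    list(
      mu_pH0 = mu_pH0, sigma_pH0 = sigma_pH0, sigma_pH = sigma_pH,
      lambda = lambda, delta_Air = delta_Air, delta_MAP1 = delta_MAP1,
      delta_MAP2 = delta_MAP2, n = n, theta = theta, pH0 = pH0
    ),
    class = "ph_params"
  )
}

#' @export
print.ph_params <- function(x, ...) {
  cat("<ph_params>\n")
  flat <- unlist(x[setdiff(names(x), "pH0")])
  print(round(flat, 4))
  if (!is.null(x$pH0)) {
    cat(sprintf("pH0 (%d batches): %s\n", length(x$pH0),
                paste(round(x$pH0, 3), collapse = ", ")))
  }
  invisible(x)
}

delta_for <- function(params, atmosphere) {
  atmosphere <- match_atmosphere(atmosphere)
  unlist(params[paste0("delta_", atmosphere)], use.names = FALSE)
}

# lactate^n with the convention 0^n := 0 for n > 0; 0 with n <= 0 is
# undefined and yields NaN so that invalid states are rejected upstream.
lactate_power <- function(lactate, n) {
  if (any(lactate < 0)) {
    abort("`lactate` must be >= 0 (% w/w).")
  }
  out <- lactate^n
  zero <- lactate == 0
  if (any(zero)) {
    out[zero] <- if (n > 0) 0 else NaN
  }
  out
}

#' Acidification rate from the log-linear lactate/atmosphere model
#'
#' Computes `beta = exp(lambda * lactate^n + delta)`, the rate (pH units per
#' day) at which pH decreases during the acidification phase, for a given
#' lactate dose and atmosphere effect. Vectorised over `lactate`.
#'
#' `0^n` is taken as 0 for `n > 0`; for `lactate = 0` with `n <= 0` the rate
#' is undefined and `NaN` is returned (such states are rejected by the
#' sampler via a `-Inf` log posterior).
#'
#' @param lambda Lactate slope on the log-rate scale.
#' @param n Scale exponent on the lactate dose.
#' @param delta Additive atmosphere effect on the log rate.
#' @param lactate Lactate dose(s) in % w/w (>= 0).
#'
#' @return Numeric vector of rates in pH units/day.
#' @examples
#' # zero lactate under the CO2/N2 atmosphere: fastest acidification
#' acidification_rate(-0.095, 1, -2.339, lactate = 0)
#' @export
acidification_rate <- function(lambda, n, delta, lactate) {
  exp(lambda * lactate_power(lactate, n) + delta)
}

#' Expected pH under the two-phase model
#'
#' Mean pH at storage time `day`: `pH0 - beta * day` during the acidification
#' phase (`day < theta`) and the constant `pH0 - beta * theta` afterwards.
#' Continuous at the breakpoint and non-increasing in time. Vectorised over
#' `day`.
#'
#' @param params A [ph_params()] state.
#' @param lactate Lactate dose in % w/w.
#' @param atmosphere One of `"Air"`, `"MAP1"`, `"MAP2"` (case-insensitive).
#' @param day Storage time(s) in days (>= 0).
#' @param pH0 Initial pH of the batch; defaults to the population mean
#'   `params$mu_pH0`.
#'
#' @return Numeric vector of expected pH values.
#' @examples
#' mean_ph(ph_params(), lactate = 2, atmosphere = "Air", day = 15)
#' @export
mean_ph <- function(params, lactate, atmosphere, day, pH0 = params$mu_pH0) {
  if (any(day < 0)) abort("`day` must be >= 0.")
  beta <- acidification_rate(params$lambda, params$n,
                             delta_for(params, atmosphere), lactate)
  if (any(!is.finite(beta))) {
    abort("Non-finite acidification rate for this parameter state.")
  }
  pH0 - beta * pmin(day, params$theta)
}

# Observation-side bookkeeping shared by the likelihood and the sampler:
# per-observation response, time, batch index and condition covariates.
prep_obs <- function(data, batch_levels = NULL) {
  data <- validate_ph_data(data)
  if (is.null(batch_levels)) batch_levels <- unique(data$batch_id)
  ridx <- match(data$batch_id, batch_levels)
  if (anyNA(ridx)) {
    abort(sprintf("Unknown batch id(s): %s",
                  paste(unique(data$batch_id[is.na(ridx)]), collapse = ", ")))
  }
  list(
    y = data$pH,
    t = data$day,
    lact = data$lactate_pct,
    atm_idx = match(data$atmosphere, ATMOSPHERES),
    batch_idx = ridx,
    batch_levels = batch_levels,
    n_obs = nrow(data)
  )
}

# Minimal structural validation of an observation table.
validate_ph_data <- function(data) {
  required <- c("batch_id", "lactate_pct", "atmosphere", "day", "pH")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("Data is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  data$atmosphere <- match_atmosphere(data$atmosphere)
  if (any(data$day < 0)) abort("Storage `day` must be >= 0.")
  if (any(data$lactate_pct < 0)) abort("`lactate_pct` must be >= 0.")
  if (any(!is.finite(data$pH))) abort("All `pH` values must be finite.")
  data
}

#' Observation log likelihood
#'
#' Sum of Gaussian log densities of the observed pH values around their
#' model means with standard deviation `sigma_pH`. States producing a
#' non-finite mean (e.g. zero lactate with a non-positive scale exponent)
#' yield `-Inf` so the sampler rejects them.
#'
#' The per-batch latent initial pH values must be supplied in `params$pH0`,
#' named by batch id. The hierarchical distribution of those latent values is
#' part of [log_prior()], not of the likelihood, so that the deviance used
#' for DIC is the observation-model deviance only.
#'
#' @param data Observation table with columns `batch_id`, `lactate_pct`,
#'   `atmosphere`, `day`, `pH`.
#' @param params A [ph_params()] state with `pH0` set.
#'
#' @return A single log-density value (possibly `-Inf`).
#' @export
log_likelihood <- function(data, params) {
  if (nrow(data) == 0) return(0)
  if (is.null(params$pH0)) abort("`params$pH0` must hold per-batch initial pH values.")
  obs <- prep_obs(data, batch_levels = names(params$pH0))
  deltas <- c(params$delta_Air, params$delta_MAP1, params$delta_MAP2)
  beta <- exp(params$lambda * lactate_power(obs$lact, params$n) +
                deltas[obs$atm_idx])
  m <- params$pH0[obs$batch_idx] - beta * pmin(obs$t, params$theta)
  if (any(!is.finite(m))) return(-Inf)
  if (params$sigma_pH == 0) {
    return(if (all(obs$y == m)) Inf else -Inf)
  }
  sum(dnorm(obs$y, m, params$sigma_pH, log = TRUE))
}

#' Joint log prior (including the batch hierarchy)
#'
#' Sum of the prior log densities of all free population-level parameters of
#' the given model variant, plus the hierarchical term: the Gaussian log
#' density of each batch's latent initial pH around
#' `(mu_pH0, sigma_pH0)`. Uniform priors contribute `-Inf` outside their
#' support and half-normal priors `-Inf` for negative values.
#'
#' @param params A [ph_params()] state (with `pH0` optionally set; a missing
#'   or empty `pH0` contributes no hierarchical term).
#' @param variant A [ph_variant()]. Fixed parameters of the variant must
#'   match the values in `params`.
#'
#' @return A single log-density value (possibly `-Inf`).
#' @export
log_prior <- function(params, variant = ph_variant("M3")) {
  pr <- variant$priors
  if (variant$n_fixed && params$n != variant$n_value) {
    abort(sprintf("Variant %s fixes n = %g but params$n = %g.",
                  variant$name, variant$n_value, params$n))
  }
  if (variant$theta_fixed && params$theta != variant$theta_value) {
    abort(sprintf("Variant %s fixes theta = %g but params$theta = %g.",
                  variant$name, variant$theta_value, params$theta))
  }
  lp <- prior_logdens(pr$mu_pH0, params$mu_pH0) +
    prior_logdens(pr$sigma_pH0, params$sigma_pH0) +
    prior_logdens(pr$sigma_pH, params$sigma_pH) +
    prior_logdens(pr$lambda, params$lambda) +
    prior_logdens(pr$delta_Air, params$delta_Air) +
    prior_logdens(pr$delta_MAP1, params$delta_MAP1) +
    prior_logdens(pr$delta_MAP2, params$delta_MAP2)
  if (!variant$n_fixed) lp <- lp + prior_logdens(pr$n, params$n)
  if (!variant$theta_fixed) lp <- lp + prior_logdens(pr$theta, params$theta)
  if (!is.null(params$pH0) && length(params$pH0) > 0) {
    if (params$sigma_pH0 < 0) return(-Inf)
    if (params$sigma_pH0 == 0) {
      lp <- lp + if (all(params$pH0 == params$mu_pH0)) Inf else -Inf
    } else {
      lp <- lp + sum(dnorm(params$pH0, params$mu_pH0, params$sigma_pH0,
                           log = TRUE))
    }
  }
  lp
}
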