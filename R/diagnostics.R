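#' Gelman-Rubin potential scale reduction factor
#'
#' Classical PSRF per sampled quantity, from the between-chain (B) and
#' within-chain (W) variances of the retained draws:
#' `Rhat = sqrt(max(W, (n-1)/n * W + B/n) / W)`. The pooled-variance
#' estimate is floored at W so that under-dispersed chains (e.g. chains
#' holding identical draws) report exactly 1 rather than a value slightly
#' below it; values well above 1 indicate non-convergence.
#'
#' @param fit A [fit_ph_model()] result with at least two chains.
#' @param parameters Optional subset of parameter names; defaults to every
#'   sampled quantity (free parameters and latent batch values).
#'
#' @return A tibble with columns `parameter` and `rhat`.
#' @export
gelman_rubin <- function(fit, parameters = NULL) {
  stopifnot(inherits(fit, "ph_fit"))
  if (length(fit$draws) < 2) {
    abort("Gelman-Rubin needs >= 2 chains; re-run with a multi-chain config.")
  }
  n <- nrow(fit$draws[[1]])
  if (n < 10) abort("Need >= 10 retained draws per chain.")
  params <- parameters %||% monitored_params(fit)
  rhat <- vapply(params, function(p) {
    psrf(lapply(fit$draws, function(d) d[, p]))
  }, numeric(1))
  tibble::tibble(parameter = params, rhat = unname(rhat))
}

# Quantities that actually vary in the trace (free population-level
# parameters plus latent batch values).
monitored_params <- function(fit) {
  cn <- colnames(fit$draws[[1]])
  latent <- grep("^pH0\\[", cn, value = TRUE)
  c(intersect(cn, fit$free_params), latent)
}

psrf <- function(chains) {
  m <- length(chains)
  n <- length(chains[[1]])
  means <- vapply(chains, mean, numeric(1))
  W <- mean(vapply(chains, var, numeric(1)))
  B <- n * var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  var_plus <- (n - 1) / n * W + B / n
  sqrt(max(var_plus, W) / W)
}

#' Geweke convergence z-scores
#'
#' Compares the mean of an early window of each chain with the mean of a
#' late window, standardised by spectral-density-at-zero standard errors
#' (batch-means estimator with batch size about the square root of the
#' window length). Under convergence z is asymptotically standard normal.
#' A chain with (numerically) constant windows returns z = 0 with a
#' warning.
#'
#' @param fit A [fit_ph_model()] result.
#' @param first_frac Fraction of each chain in the early window
#'   (default 0.1).
#' @param last_frac Fraction in the late window (default 0.5). The windows
#'   must not overlap: `first_frac + last_frac <= 1`.
#' @param parameters Optional subset of parameter names.
#'
#' @return A tibble with columns `parameter`, `chain`, `z`.
#' @export
geweke <- function(fit, first_frac = 0.1, last_frac = 0.5,
                   parameters = NULL) {
  stopifnot(inherits(fit, "ph_fit"))
  if (first_frac <= 0 || last_frac <= 0 || first_frac + last_frac > 1) {
    abort("Geweke windows overlap: need first_frac + last_frac <= 1 (both > 0).")
  }
  params <- parameters %||% monitored_params(fit)
  out <- purrr::map_dfr(seq_along(fit$draws), function(ch) {
    d <- fit$draws[[ch]]
    tibble::tibble(
      parameter = params,
      chain = ch,
      z = unname(vapply(params, function(p) {
        geweke_z(d[, p], first_frac, last_frac)
      }, numeric(1)))
    )
  })
  out
}

geweke_z <- function(x, first_frac, last_frac) {
  n <- length(x)
  n1 <- floor(first_frac * n)
  n2 <- floor(last_frac * n)
  if (n1 < 10 || n2 < 10) {
    abort("Chain too short: both Geweke windows need >= 10 draws.")
  }
  x1 <- x[seq_len(n1)]
  x2 <- x[seq.int(n - n2 + 1, n)]
  se1sq <- batch_means_var(x1)
  se2sq <- batch_means_var(x2)
  denom <- sqrt(se1sq + se2sq)
  if (denom == 0) {
    warn("Degenerate (constant) chain windows in Geweke diagnostic; z set to 0.")
    return(0)
  }
  (mean(x1) - mean(x2)) / denom
}

# Batch-means estimate of Var(mean(x)) for a (possibly autocorrelated)
# chain segment; batch size ~ sqrt(length).
batch_means_var <- function(x) {
  m <- length(x)
  b <- max(1L, floor(sqrt(m)))
  nb <- m %/% b
  bm <- colMeans(matrix(x[seq_len(nb * b)], nrow = b))
  if (nb < 2) return(0)
  var(bm) / nb
}

#' Convergence report for a fitted model
#'
#' Combines [gelman_rubin()] and [geweke()] against configurable pass
#' thresholds (defaults: Rhat < 1.1 and |z| < 2 for every monitored
#' quantity).
#'
#' @param fit A [fit_ph_model()] result.
#' @param rhat_threshold Upper limit on acceptable Rhat.
#' @param z_threshold Upper limit on acceptable |Geweke z|.
#' @inheritParams geweke
#'
#' @return A list of class `ph_diagnostics` with elements `rhat` (tibble),
#'   `geweke` (tibble), `passed` (logical), and `failed_parameters`.
#' @export
diagnose <- function(fit, rhat_threshold = 1.1, z_threshold = 2,
                     first_frac = 0.1, last_frac = 0.5) {
  rh <- gelman_rubin(fit)
  gw <- geweke(fit, first_frac, last_frac)
  bad_r <- rh$parameter[rh$rhat >= rhat_threshold]
  bad_g <- unique(gw$parameter[abs(gw$z) >= z_threshold])
  structure(
    list(
      rhat = rh,
      geweke = gw,
      rhat_threshold = rhat_threshold,
      z_threshold = z_threshold,
      passed = length(bad_r) == 0 && length(bad_g) == 0,
      failed_parameters = union(bad_r, bad_g)
    ),
    class = "ph_diagnostics"
  )
}

#' @export
print.ph_diagnostics <- function(x, ...) {
  cat(sprintf(
    "<ph_diagnostics> %s (Rhat < %g, |z| < %g); max Rhat = %.4f\n",
    if (x$passed) "PASSED" else
      paste("FAILED for", paste(x$failed_parameters, collapse = ", ")),
    x$rhat_threshold, x$z_threshold, max(x$rhat$rhat)
  ))
  invisible(x)
}
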