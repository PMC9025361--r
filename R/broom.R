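#' Tidy a fitted acidification model
#'
#' Returns one row per sampled quantity with the posterior median as
#' `estimate` and the 95% credibility interval bounds as `conf.low` /
#' `conf.high`, broom-style. Latent per-batch initial pH values are
#' included unless `latent = FALSE`.
#'
#' @param x A [fit_ph_model()] result.
#' @param latent Include the `pH0[batch]` rows? Default `TRUE`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `conf.low`,
#'   `conf.high`.
#' @export
tidy.ph_fit <- function(x, latent = TRUE, ...) {
  s <- summarize_posterior(x)
  out <- tibble::tibble(
    term = s$parameter,
    estimate = s$median,
    conf.low = s$lower,
    conf.high = s$upper
  )
  if (!latent) out <- out[!grepl("^pH0\\[", out$term), ]
  out
}

#' One-row summary of a fitted acidification model
#'
#' @param x A [fit_ph_model()] result.
#' @param ... Unused.
#' @return A one-row tibble: variant, chain/draw counts, observation and
#'   batch counts, mean deviance and the mean acceptance rate across
#'   Metropolis blocks.
#' @export
glance.ph_fit <- function(x, ...) {
  acc <- unlist(x$acceptance)
  tibble::tibble(
    variant = x$variant$name,
    n_chains = length(x$draws),
    draws_per_chain = nrow(x$draws[[1]]),
    pooled_draws = length(x$draws) * nrow(x$draws[[1]]),
    n_obs = x$n_obs,
    n_batches = length(x$batch_levels),
    mean_deviance = mean(unlist(x$deviance)),
    mean_acceptance = if (length(acc) > 0) mean(acc) else NA_real_
  )
}

#' Augment observations with fitted values and residuals
#'
#' Adds `.fitted` (the two-phase mean at the posterior medians, using each
#' observation's batch estimate of initial pH) and `.resid`
#' (observed - fitted) to the data.
#'
#' @param x A [fit_ph_model()] result.
#' @param data The observation table the model was fitted to.
#' @param ... Unused.
#' @return The data with `.fitted` and `.resid` columns appended.
#' @export
augment.ph_fit <- function(x, data, ...) {
  gof <- goodness_of_fit(summarize_posterior(x), data)
  dplyr::rename(gof, .fitted = "adjusted", .resid = "residual")
}
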