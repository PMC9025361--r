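#' Deviance Information Criterion of a fitted variant
#'
#' Uses the Spiegelhalter construction: the mean posterior deviance
#' `Dbar` (deviance = -2 x observation log likelihood, stored per retained
#' draw), the plug-in deviance `Dhat` at the posterior mean of every
#' sampled quantity (population parameters and latent batch initial pH),
#' the effective number of parameters `pD = Dbar - Dhat`, and
#' `DIC = Dbar + pD = 2 Dbar - Dhat`. Lower is better. Absolute DIC values
#' depend on the penalty definition of the engine that produced them, so
#' comparisons are only meaningful between fits produced by this package on
#' the same dataset.
#'
#' @param fit A [fit_ph_model()] result.
#' @param data The dataset the model was fitted to (checked against the
#'   observation count recorded in the fit).
#'
#' @return A one-row tibble of class `ph_dic` with columns `variant`,
#'   `dbar`, `dhat`, `pd`, `dic`.
#' @export
compute_dic <- function(fit, data) {
  stopifnot(inherits(fit, "ph_fit"))
  data <- validate_ph_data(tibble::as_tibble(data))
  if (nrow(data) != fit$n_obs) {
    abort(sprintf(
      "Dataset has %d observations but the fit recorded %d; DIC needs the fitted dataset.",
      nrow(data), fit$n_obs
    ))
  }
  dbar <- mean(unlist(fit$deviance))
  pm <- colMeans(pooled_draws(fit))
  params <- params_from_draw(pm, fit$batch_levels)
  dhat <- -2 * log_likelihood(data, params)
  out <- tibble::tibble(
    variant = fit$variant$name,
    dbar = dbar,
    dhat = dhat,
    pd = dbar - dhat,
    dic = 2 * dbar - dhat
  )
  class(out) <- c("ph_dic", class(out))
  out
}

# Rebuild a ph_params state from one named draw (or posterior-mean) vector.
params_from_draw <- function(x, batch_levels) {
  p <- ph_params(
    mu_pH0 = x[["mu_pH0"]], sigma_pH0 = x[["sigma_pH0"]],
    sigma_pH = x[["sigma_pH"]], lambda = x[["lambda"]],
    delta_Air = x[["delta_Air"]], delta_MAP1 = x[["delta_MAP1"]],
    delta_MAP2 = x[["delta_MAP2"]], n = x[["n"]], theta = x[["theta"]]
  )
  if (length(batch_levels) > 0) {
    p$pH0 <- setNames(x[sprintf("pH0[%s]", batch_levels)], batch_levels)
  }
  p
}

#' Pick the best variant by DIC
#'
#' Returns the name of the variant with the lowest DIC. Exact ties are
#' broken towards the variant with fewer free parameters (parsimony), then
#' by variant order.
#'
#' @param dic_table A tibble combining [compute_dic()] rows (>= 1).
#' @return The winning variant name (character scalar).
#' @examples
#' dics <- tibble::tibble(variant = c("M1", "M2", "M3", "M4"),
#'                        dic = c(-274.8, -271.0, -296.5, -294.1))
#' select_model(dics)
#' @export
select_model <- function(dic_table) {
  if (is.null(dic_table) || nrow(dic_table) == 0) {
    abort("`dic_table` must contain at least one DIC result.")
  }
  nfree <- vapply(dic_table$variant,
                  function(v) n_free_params(ph_variant(v)), numeric(1))
  ord <- order(dic_table$dic, nfree, dic_table$variant)
  dic_table$variant[ord[1]]
}

#' Posterior medians and 95% credibility intervals
#'
#' Pools the retained draws of all chains and reports, per sampled quantity
#' (including each batch's latent initial pH), the median as point estimate
#' and the 2.5% / 97.5% quantiles as the credibility interval. Quantiles
#' use linear interpolation between order statistics.
#'
#' @param fit A [fit_ph_model()] result.
#' @return A tibble of class `ph_summary` with columns `parameter`,
#'   `median`, `lower`, `upper`, `free`.
#' @export
summarize_posterior <- function(fit) {
  stopifnot(inherits(fit, "ph_fit"))
  d <- pooled_draws(fit)
  qs <- t(apply(d, 2, quantile, probs = c(0.025, 0.5, 0.975), names = FALSE))
  out <- tibble::tibble(
    parameter = colnames(d),
    median = unname(qs[, 2]),
    lower = unname(qs[, 1]),
    upper = unname(qs[, 3]),
    free = colnames(d) %in% monitored_params(fit)
  )
  class(out) <- c("ph_summary", class(out))
  attr(out, "batch_levels") <- fit$batch_levels
  attr(out, "variant") <- fit$variant$name
  out
}

# Point-estimate ph_params state from a posterior summary.
params_from_summary <- function(summary) {
  x <- setNames(summary$median, summary$parameter)
  params_from_draw(x, attr(summary, "batch_levels") %||%
                     sub("^pH0\\[(.*)\\]$", "\\1",
                         grep("^pH0\\[", summary$parameter, value = TRUE)))
}

#' Adjusted values and residuals at the posterior point estimates
#'
#' Computes, for every observation, the model-adjusted pH (the two-phase
#' mean evaluated at the posterior medians, using the observation's batch
#' latent initial pH estimate) and the residual observed - adjusted, for
#' goodness-of-fit inspection.
#'
#' @param summary A [summarize_posterior()] result containing point
#'   estimates for every batch present in `data`.
#' @param data Observation table.
#' @return The data as a tibble with extra columns `adjusted` and
#'   `residual`.
#' @export
goodness_of_fit <- function(summary, data) {
  stopifnot(inherits(summary, "ph_summary"))
  data <- validate_ph_data(tibble::as_tibble(data))
  params <- params_from_summary(summary)
  missing_b <- setdiff(unique(data$batch_id), names(params$pH0))
  if (length(missing_b) > 0) {
    abort(sprintf("No posterior estimate of initial pH for batch(es): %s",
                  paste(missing_b, collapse = ", ")))
  }
  obs <- prep_obs(data, batch_levels = names(params$pH0))
  deltas <- c(params$delta_Air, params$delta_MAP1, params$delta_MAP2)
  beta <- exp(params$lambda * lactate_power(obs$lact, params$n) +
                deltas[obs$atm_idx])
  adjusted <- params$pH0[obs$batch_idx] - beta * pmin(obs$t, params$theta)
  dplyr::mutate(data, adjusted = unname(adjusted),
                residual = .data$pH - .data$adjusted)
}
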