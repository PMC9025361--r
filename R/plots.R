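#' Plot a simulated kinetics band
#'
#' Median pH curve with its pointwise 95% credible ribbon.
#'
#' @param object A [simulate_kinetics()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ph_band <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$day, y = .data$median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.25) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::labs(
      x = "Storage time (days)", y = "pH",
      title = sprintf("Simulated pH kinetics: %g%% w/w lactate, %s",
                      object$lactate_pct[1], object$atmosphere[1]),
      subtitle = "Median and pointwise 95% credible band"
    )
}

#' Trace plot of a fitted model
#'
#' Retained draws per chain for each monitored parameter, for visual
#' convergence assessment.
#'
#' @param object A [fit_ph_model()] result.
#' @param parameters Optional subset of parameter names (default: free
#'   population-level parameters only).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ph_fit <- function(object, parameters = NULL, ...) {
  params <- parameters %||% intersect(colnames(object$draws[[1]]),
                                      object$free_params)
  long <- purrr::map_dfr(seq_along(object$draws), function(ch) {
    d <- object$draws[[ch]][, params, drop = FALSE]
    tibble::tibble(
      chain = factor(ch),
      iteration = rep(seq_len(nrow(d)), times = length(params)),
      parameter = rep(params, each = nrow(d)),
      value = as.vector(d)
    )
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value,
                                     colour = .data$chain)) +
    ggplot2::geom_line(alpha = 0.6, linewidth = 0.2) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "Retained iteration", y = NULL,
                  title = "MCMC traces by chain")
}

#' Plot the acidification rate against lactate dose
#'
#' @param object A [rate_curve()] result (may contain several atmospheres
#'   bound together).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ph_rate_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lactate_pct, y = .data$rate,
                                       colour = .data$atmosphere)) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::labs(x = "Lactate dose (% w/w)",
                  y = "Acidification rate (pH units/day)",
                  colour = "Atmosphere",
                  title = "Acidification rate at the posterior point estimates")
}

#' Residuals-versus-adjusted plot
#'
#' Goodness-of-fit view: residuals (observed - adjusted pH) against the
#' adjusted values; a well-specified fit shows no trend.
#'
#' @param gof A [goodness_of_fit()] result.
#' @return A ggplot object.
#' @export
plot_residuals <- function(gof) {
  stopifnot(all(c("adjusted", "residual") %in% names(gof)))
  ggplot2::ggplot(gof, ggplot2::aes(x = .data$adjusted, y = .data$residual)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "Adjusted pH", y = "Residual (observed - adjusted)",
                  title = "Residuals vs adjusted values")
}

#' Prior and posterior density overlay
#'
#' Compares the marginal posterior of selected parameters with their prior
#' densities, showing how much the data moved each parameter.
#'
#' @param fit A [fit_ph_model()] result.
#' @param parameters Parameters to show (default: the free population-level
#'   parameters with proper priors).
#' @return A ggplot object.
#' @export
plot_prior_posterior <- function(fit, parameters = NULL) {
  stopifnot(inherits(fit, "ph_fit"))
  params <- parameters %||% fit$free_params
  pr <- fit$variant$priors
  d <- pooled_draws(fit)
  post <- purrr::map_dfr(params, function(p) {
    tibble::tibble(parameter = p, value = d[, p])
  })
  prior_curves <- purrr::map_dfr(params, function(p) {
    spec <- pr[[p]]
    rng <- range(d[, p])
    pad <- 0.25 * diff(rng) + 1e-9
    xs <- seq(rng[1] - pad, rng[2] + pad, length.out = 200)
    dens <- vapply(xs, function(x) exp(prior_logdens(spec, x)), numeric(1))
    tibble::tibble(parameter = p, value = xs, density = dens)
  })
  ggplot2::ggplot(post, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "seagreen", alpha = 0.4, colour = NA) +
    ggplot2::geom_line(data = prior_curves,
                       ggplot2::aes(y = .data$density), colour = "steelblue") +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "Density",
                  title = "Posterior (filled) vs prior (line)")
}
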