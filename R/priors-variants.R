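#' Prior specification for the acidification model
#'
#' Returns the default priors used throughout: an informative normal prior
#' on the mean initial pH taken from earlier measurements on fresh poultry
#' sausages, weakly informative half-normals on the two standard deviations,
#' and non-informative uniforms on the lactate slope, atmosphere effects and
#' (when free) the scale exponent and stabilisation time. Any component can
#' be overridden by passing a replacement descriptor.
#'
#' Distribution descriptors are lists: `normal(mean, sd)`,
#' `half_normal(sd)` (the absolute value of a centred normal) and
#' `uniform(lo, hi)`. The second argument of the normal family is always a
#' standard deviation, never a variance or precision.
#'
#' @param ... Named replacement descriptors, e.g.
#'   `mu_pH0 = prior_normal(6, 0.5)`.
#'
#' @return A named list of prior descriptors of class `ph_priors`.
#' @examples
#' ph_priors()$theta
#' ph_priors(theta = prior_uniform(10, 20))$theta
#' @export
ph_priors <- function(...) {
  defaults <- list(
    mu_pH0 = prior_normal(5.84, 0.11),
    sigma_pH0 = prior_half_normal(0.1),
    sigma_pH = prior_half_normal(0.1),
    delta_Air = prior_uniform(-10, 10),
    delta_MAP1 = prior_uniform(-10, 10),
    delta_MAP2 = prior_uniform(-10, 10),
    lambda = prior_uniform(-1, 1),
    n = prior_uniform(-3, 3),
    theta = prior_uniform(8, 22)
  )
  override <- list(...)
  bad <- setdiff(names(override), names(defaults))
  if (length(bad) > 0) {
    abort(sprintf("Unknown prior component(s): %s", paste(bad, collapse = ", ")))
  }
  structure(modifyList(defaults, override), class = "ph_priors")
}

#' @rdname ph_priors
#' @param mean,sd,lo,hi Distribution parameters (`sd` is a standard
#'   deviation).
#' @export
prior_normal <- function(mean, sd) {
  stopifnot(sd > 0)
  list(dist = "normal", mean = mean, sd = sd)
}

#' @rdname ph_priors
#' @export
prior_half_normal <- function(sd) {
  stopifnot(sd > 0)
  list(dist = "half_normal", sd = sd)
}

#' @rdname ph_priors
#' @export
prior_uniform <- function(lo, hi) {
  stopifnot(hi > lo)
  list(dist = "uniform", lo = lo, hi = hi)
}

prior_logdens <- function(p, x) {
  switch(p$dist,
    normal = dnorm(x, p$mean, p$sd, log = TRUE),
    half_normal = if (x < 0) -Inf else log(2) + dnorm(x, 0, p$sd, log = TRUE),
    uniform = if (x < p$lo || x > p$hi) -Inf else -log(p$hi - p$lo),
    abort(sprintf("Unknown prior distribution %s", sQuote(p$dist)))
  )
}

# Draw a starting value from a prior, shrinking uniform supports by 10%
# towards the centre so chains never start on a -Inf boundary.
prior_draw_start <- function(p) {
  switch(p$dist,
    normal = rnorm(1, p$mean, p$sd),
    half_normal = abs(rnorm(1, 0, p$sd)) + 1e-4,
    uniform = {
      w <- p$hi - p$lo
      runif(1, p$lo + 0.05 * w, p$hi - 0.05 * w)
    }
  )
}

prior_support <- function(p) {
  switch(p$dist,
    normal = c(-Inf, Inf),
    half_normal = c(0, Inf),
    uniform = c(p$lo, p$hi)
  )
}

#' Model variants: scale exponent and stabilisation time fixed or free
#'
#' Four variants of the acidification model are compared by DIC. They differ
#' only in whether the lactate scale exponent `n` and the stabilisation time
#' `theta` are fixed constants or estimated with uniform priors:
#'
#' * `M1`: `n = 1` fixed, `theta = 15` days fixed (7 free parameters);
#' * `M2`: `theta = 15` fixed, `n` free (8);
#' * `M3`: `n = 1` fixed, `theta` free (8);
#' * `M4`: both free (9).
#'
#' The fixed values correspond to a log-linear first-order lactate effect
#' and to the producers' use-by date of 15 days.
#'
#' @param name One of `"M1"`, `"M2"`, `"M3"`, `"M4"`.
#' @param priors A [ph_priors()] specification.
#'
#' @return A list of class `ph_variant` with elements `name`, `n_fixed`,
#'   `n_value`, `theta_fixed`, `theta_value`, `priors`.
#' @examples
#' ph_variant("M3")
#' @export
ph_variant <- function(name = c("M3", "M1", "M2", "M4"), priors = ph_priors()) {
  name <- match.arg(name)
  stopifnot(inherits(priors, "ph_priors"))
  structure(
    list(
      name = name,
      n_fixed = name %in% c("M1", "M3"),
      n_value = 1,
      theta_fixed = name %in% c("M1", "M2"),
      theta_value = 15,
      priors = priors
    ),
    class = "ph_variant"
  )
}

#' @export
print.ph_variant <- function(x, ...) {
  cat(sprintf(
    "<ph_variant %s> n: %s; theta: %s; %d free population-level parameters\n",
    x$name,
    if (x$n_fixed) sprintf("fixed at %g", x$n_value) else "free",
    if (x$theta_fixed) sprintf("fixed at %g days", x$theta_value) else "free",
    n_free_params(x)
  ))
  invisible(x)
}

# Free population-level parameter names, in sampler update order.
free_param_names <- function(variant) {
  base <- c("lambda", "delta_Air", "delta_MAP1", "delta_MAP2",
            "sigma_pH", "mu_pH0", "sigma_pH0")
  extra <- c(if (!variant$n_fixed) "n", if (!variant$theta_fixed) "theta")
  c(base, extra)
}

#' Number of free population-level parameters of a variant
#'
#' Counts the mean initial pH, the two standard deviations, the lactate
#' slope and three atmosphere effects, plus whichever of the scale exponent
#' and stabilisation time the variant leaves free (7, 8, 8 and 9 for M1-M4).
#'
#' @param variant A [ph_variant()].
#' @return Integer count.
#' @export
n_free_params <- function(variant) {
  length(free_param_names(variant))
}
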