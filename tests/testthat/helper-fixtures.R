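# Shared fixtures: small designs and fast sampler configurations.

tiny_design <- function(n_batches = 3) {
  ph_design(n_batches = n_batches, lactate_doses = c(0, 2),
            atmospheres = c("Air", "MAP2"), sampling_days = c(2, 8, 15))
}

short_config <- function(seed = 1, n_chains = 2, burn_in = 500,
                         n_iterations = 2000, thinning = 2) {
  mcmc_config(n_chains = n_chains, burn_in = burn_in,
              n_iterations = n_iterations, thinning = thinning, seed = seed)
}

# Independent per-term density oracle for the observation log likelihood:
# loops over rows, recomputes the two-phase mean from scratch.
oracle_log_likelihood <- function(data, params) {
  total <- 0
  for (i in seq_len(nrow(data))) {
    row <- data[i, ]
    d <- switch(row$atmosphere,
                Air = params$delta_Air,
                MAP1 = params$delta_MAP1,
                MAP2 = params$delta_MAP2)
    lp <- if (row$lactate_pct == 0) {
      if (params$n > 0) 0 else NaN
    } else row$lactate_pct^params$n
    beta <- exp(params$lambda * lp + d)
    m <- params$pH0[[row$batch_id]] -
      beta * if (row$day < params$theta) row$day else params$theta
    total <- total + dnorm(row$pH, m, params$sigma_pH, log = TRUE)
  }
  total
}

# Independent per-term oracle for the joint log prior under a variant,
# written directly from the prior table.
oracle_log_prior <- function(params, variant) {
  unif <- function(x, lo, hi) if (x < lo || x > hi) -Inf else -log(hi - lo)
  halfn <- function(x, s) if (x < 0) -Inf else log(2) + dnorm(x, 0, s, log = TRUE)
  lp <- dnorm(params$mu_pH0, 5.84, 0.11, log = TRUE) +
    halfn(params$sigma_pH0, 0.1) + halfn(params$sigma_pH, 0.1) +
    unif(params$lambda, -1, 1) +
    unif(params$delta_Air, -10, 10) + unif(params$delta_MAP1, -10, 10) +
    unif(params$delta_MAP2, -10, 10)
  if (!variant$n_fixed) lp <- lp + unif(params$n, -3, 3)
  if (!variant$theta_fixed) lp <- lp + unif(params$theta, 8, 22)
  lp + sum(dnorm(params$pH0, params$mu_pH0, params$sigma_pH0, log = TRUE))
}

# Textbook potential-scale-reduction oracle on a list of chains, with the
# same under-dispersion floor the package documents.
oracle_psrf <- function(chains) {
  m <- length(chains)
  n <- length(chains[[1]])
  W <- mean(sapply(chains, var))
  B <- n * var(sapply(chains, mean))
  vhat <- (n - 1) / n * W + B / n
  sqrt(max(vhat, W) / W)
}

# Geweke z oracle: window means standardised by batch-means standard errors.
oracle_geweke_z <- function(x, first = 0.1, last = 0.5) {
  n <- length(x)
  x1 <- x[1:floor(first * n)]
  x2 <- x[(n - floor(last * n) + 1):n]
  bm_var <- function(z) {
    b <- max(1, floor(sqrt(length(z))))
    nb <- length(z) %/% b
    bm <- colMeans(matrix(z[1:(nb * b)], nrow = b))
    var(bm) / nb
  }
  (mean(x1) - mean(x2)) / sqrt(bm_var(x1) + bm_var(x2))
}

# Build a ph_params state with named per-batch pH0 values filled in.
params_with_pH0 <- function(..., batch_ids = c("B01", "B02", "B03"),
                            pH0_values = NULL) {
  p <- ph_params(...)
  if (is.null(pH0_values)) pH0_values <- rep(p$mu_pH0, length(batch_ids))
  p$pH0 <- stats::setNames(pH0_values, batch_ids)
  p
}
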