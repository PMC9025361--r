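test_that("DIC identity and degenerate-trace penalty", {
  sim <- simulate_ph_data(tiny_design(2), ph_params(theta = 15), seed = 41)
  fit <- fit_ph_model(sim, ph_variant("M1"), short_config(seed = 43,
                      n_chains = 1, burn_in = 200, n_iterations = 400))
  dic <- compute_dic(fit, sim)
  expect_equal(dic$dic, 2 * dic$dbar - dic$dhat)
  expect_equal(dic$dic, dic$dbar + dic$pd)

  # a trace that never moves has zero effective parameters
  truth <- ph_truth(sim)
  frozen <- fit_ph_model(sim, ph_variant("M1"),
                         short_config(seed = 47, n_chains = 1,
                                      burn_in = 50, n_iterations = 100),
                         fixed = c(truth[setdiff(names(truth), "pH0")],
                                   list(pH0 = truth$pH0)))
  dic0 <- compute_dic(frozen, sim)
  expect_equal(dic0$pd, 0, tolerance = 1e-10)
  expect_equal(dic0$dic, dic0$dhat, tolerance = 1e-10)
})

test_that("DIC matches a quadrature oracle on a conjugate normal-mean toy", {
  # all observations at day 0 in one batch: y ~ N(pH0, sigma) with known
  # sigma and pH0 ~ N(m0, s0); only the latent pH0 is sampled (conjugate
  # Gibbs), so the DIC has a closed form up to quadrature
  m0 <- 5.84; s0 <- 0.11; sigma <- 0.15
  y <- c(6.35, 6.52, 6.44, 6.61, 6.38, 6.50)
  d <- tibble::tibble(batch_id = "B01", lactate_pct = 0, atmosphere = "Air",
                      day = 0, pH = y)
  fit <- fit_ph_model(
    d, ph_variant("M1"),
    mcmc_config(n_chains = 1, burn_in = 1000, n_iterations = 30000,
                thinning = 2, seed = 51),
    fixed = list(mu_pH0 = m0, sigma_pH0 = s0, sigma_pH = sigma,
                 lambda = -0.095, delta_Air = -2.43, delta_MAP1 = -2.487,
                 delta_MAP2 = -2.339)
  )
  dic <- compute_dic(fit, d)

  n <- length(y)
  post_prec <- n / sigma^2 + 1 / s0^2
  post_mean <- (sum(y) / sigma^2 + m0 / s0^2) / post_prec
  post_sd <- sqrt(1 / post_prec)
  dev_fun <- function(mu) -2 * vapply(mu, function(m) {
    sum(dnorm(y, m, sigma, log = TRUE))
  }, numeric(1))
  ed <- stats::integrate(function(m) dev_fun(m) * dnorm(m, post_mean, post_sd),
                         post_mean - 8 * post_sd, post_mean + 8 * post_sd)$value
  dic_oracle <- 2 * ed - dev_fun(post_mean)
  expect_equal(dic$dic, dic_oracle, tolerance = 0.01)
  # quadratic deviance: pD = n * Var_post(mu) / sigma^2 exactly
  expect_equal(dic$pd, n / post_prec / sigma^2, tolerance = 0.05)
})

test_that("DIC demands the dataset the trace was fitted to", {
  sim <- simulate_ph_data(tiny_design(2), ph_params(), seed = 53)
  fit <- fit_ph_model(sim, ph_variant("M1"), short_config(seed = 55,
                      n_chains = 1, burn_in = 100, n_iterations = 200))
  expect_error(compute_dic(fit, sim[1:5, ]), "observations")
})

test_that("the lowest DIC wins, with parsimony tie-breaks", {
  published <- tibble::tibble(
    variant = c("M1", "M2", "M3", "M4"),
    dic = c(-274.8, -271.0, -296.5, -294.1)
  )
  expect_equal(select_model(published), "M3")
  tie <- tibble::tibble(variant = c("M3", "M4"), dic = c(-5, -5))
  expect_equal(select_model(tie), "M3")
  expect_equal(select_model(tibble::tibble(variant = "M2", dic = 1)), "M2")
  expect_error(select_model(tibble::tibble(variant = character(),
                                           dic = numeric())), "at least one")
})

test_that("posterior summaries are pooled medians with 95% intervals", {
  f <- local({
    draws <- list(matrix(1:500, ncol = 1, dimnames = list(NULL, "theta")),
                  matrix(501:1000, ncol = 1, dimnames = list(NULL, "theta")))
    structure(list(draws = draws, deviance = list(rep(0, 500), rep(0, 500)),
                   acceptance = list(), scales_at_freeze = list(),
                   scales_final = list(), variant = ph_variant("M3"),
                   config = mcmc_config(n_chains = 2, seed = 1),
                   free_params = "theta", batch_levels = character(0),
                   n_obs = 0),
              class = "ph_fit")
  })
  s <- summarize_posterior(f)
  expect_equal(s$median[s$parameter == "theta"], 500.5)
  expect_true(all(s$lower <= s$median & s$median <= s$upper))
})

test_that("quantiles use linear interpolation between order statistics", {
  # independently coded interpolation oracle
  lin_quantile <- function(x, p) {
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  set.seed(57)
  x <- rnorm(501)
  for (p in c(0.025, 0.5, 0.975)) {
    expect_equal(unname(quantile(x, p)), lin_quantile(x, p), tolerance = 1e-12)
  }
})

test_that("residuals vanish when the summary equals the generating truth", {
  truth0 <- ph_params(sigma_pH0 = 0, sigma_pH = 0, theta = 15)
  sim <- simulate_ph_data(tiny_design(3), truth0, seed = 61)
  truth <- ph_truth(sim)
  frozen <- fit_ph_model(sim, ph_variant("M1"),
                         short_config(seed = 63, n_chains = 1,
                                      burn_in = 20, n_iterations = 40),
                         fixed = c(list(mu_pH0 = truth$mu_pH0,
                                        sigma_pH0 = 1e-6, sigma_pH = 1e-6,
                                        lambda = truth$lambda,
                                        delta_Air = truth$delta_Air,
                                        delta_MAP1 = truth$delta_MAP1,
                                        delta_MAP2 = truth$delta_MAP2),
                                   list(pH0 = truth$pH0)))
  gof <- goodness_of_fit(summarize_posterior(frozen), sim)
  expect_equal(gof$residual, rep(0, nrow(sim)), tolerance = 1e-12)
  expect_equal(gof$adjusted, gof$pH, tolerance = 1e-12)
})

test_that("residual is observed minus adjusted", {
  sim <- simulate_ph_data(tiny_design(2), ph_params(), seed = 65)
  fit <- fit_ph_model(sim, ph_variant("M1"), short_config(seed = 67,
                      n_chains = 1, burn_in = 100, n_iterations = 200))
  gof <- goodness_of_fit(summarize_posterior(fit), sim)
  expect_equal(gof$residual, gof$pH - gof$adjusted)
  # an observation from an unknown batch cannot be adjusted
  other <- sim[1, ]; other$batch_id <- "B99"
  expect_error(goodness_of_fit(summarize_posterior(fit), other), "B99")
})

test_that("a well-specified fit recovers the noise scale without residual trend", {
  sim <- simulate_ph_data(ph_design(), ph_params(), seed = 69)
  fit <- fit_ph_model(sim, ph_variant("M3"),
                      mcmc_config(n_chains = 2, burn_in = 1000,
                                  n_iterations = 4000, thinning = 4,
                                  seed = 71))
  gof <- goodness_of_fit(summarize_posterior(fit), sim)
  expect_lt(abs(sd(gof$residual) - 0.15), 0.2 * 0.15)
  slope <- unname(coef(lm(residual ~ adjusted, data = gof))[2])
  expect_lt(abs(slope), 0.1)
})
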