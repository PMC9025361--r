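empty_data <- tibble::tibble(batch_id = character(), lactate_pct = numeric(),
                             atmosphere = character(), day = numeric(),
                             pH = numeric())

test_that("retained draw counts follow the chain configuration", {
  sim <- simulate_ph_data(tiny_design(2), ph_params(), seed = 2)
  cfg <- mcmc_config(n_chains = 2, burn_in = 100, n_iterations = 900,
                     thinning = 3, seed = 4)
  fit <- fit_ph_model(sim, ph_variant("M1"), cfg)
  expect_length(fit$draws, 2)
  expect_equal(nrow(fit$draws[[1]]), 300)
  expect_equal(nrow(pooled_draws(fit)), 600)
  expect_length(fit$deviance[[1]], 300)
  # thinning must divide the iteration count
  expect_error(mcmc_config(n_iterations = 1000, thinning = 7), "thinning")
})

test_that("sampling the prior: empty data recovers the uniform theta prior", {
  fit <- fit_ph_model(
    empty_data, ph_variant("M3"),
    mcmc_config(n_chains = 1, burn_in = 1000, n_iterations = 45000,
                thinning = 3, seed = 11)
  )
  th <- pooled_draws(fit)[, "theta"]
  expect_true(all(th > 8 & th < 22))
  # closed-form U(8, 22) quantiles
  expect_equal(unname(quantile(th, c(0.25, 0.5, 0.75))),
               c(11.5, 15, 18.5), tolerance = 0.05)
  # the informative normal prior on the mean initial pH is recovered too
  mu <- pooled_draws(fit)[, "mu_pH0"]
  expect_equal(mean(mu), 5.84, tolerance = 0.01)
  expect_equal(sd(mu), 0.11, tolerance = 0.05)
})

test_that("MH updates of the hierarchical mean match the conjugate closed form", {
  # two batches with pinned latent initial pH values: the posterior of
  # mu_pH0 is then exactly normal-normal (prior N(5.84, 0.11), two
  # "observations" v1, v2 with sd sigma_pH0)
  v <- c(B01 = 6.42, B02 = 6.58)
  sim <- tibble::tibble(
    batch_id = c("B01", "B02"), lactate_pct = 0, atmosphere = "Air",
    day = 2, pH = c(6.3, 6.5)
  )
  fixed <- list(sigma_pH0 = 0.1, sigma_pH = 0.15, lambda = -0.095,
                delta_Air = -2.43, delta_MAP1 = -2.487, delta_MAP2 = -2.339,
                pH0 = v)
  fit <- fit_ph_model(sim, ph_variant("M1"),
                      mcmc_config(n_chains = 1, burn_in = 2000,
                                  n_iterations = 60000, thinning = 3,
                                  seed = 13),
                      fixed = fixed)
  prec <- 1 / 0.11^2 + 2 / 0.1^2
  post_mean <- (5.84 / 0.11^2 + sum(v) / 0.1^2) / prec
  post_sd <- sqrt(1 / prec)
  mu <- pooled_draws(fit)[, "mu_pH0"]
  expect_equal(mean(mu), post_mean, tolerance = 0.02 * post_sd / post_mean + 0.001)
  expect_equal(sd(mu), post_sd, tolerance = 0.02)
  # pinned quantities never move
  expect_equal(unique(pooled_draws(fit)[, "sigma_pH"]), 0.15)
  expect_equal(unique(pooled_draws(fit)[, "pH0[B01]"]), 6.42)
})

test_that("proposal scales adapt only during burn-in", {
  sim <- simulate_ph_data(tiny_design(2), ph_params(), seed = 6)
  fit <- fit_ph_model(sim, ph_variant("M4"), short_config(seed = 8))
  for (ch in seq_along(fit$draws)) {
    expect_identical(fit$scales_at_freeze[[ch]], fit$scales_final[[ch]])
  }
  # adaptation moved the scales away from their common initial values
  expect_gt(length(unique(round(fit$scales_final[[1]], 6))), 2)
})

test_that("acceptance rates of adapted blocks are near the 0.44 target", {
  sim <- simulate_ph_data(ph_design(n_batches = 5), ph_params(), seed = 14)
  fit <- fit_ph_model(sim, ph_variant("M3"),
                      mcmc_config(n_chains = 1, burn_in = 2000,
                                  n_iterations = 6000, thinning = 3, seed = 2))
  acc <- fit$acceptance[[1]]
  expect_true(all(acc > 0.2 & acc < 0.7))
})

test_that("identical data, config and seed give identical traces", {
  sim <- simulate_ph_data(tiny_design(2), ph_params(), seed = 3)
  cfg <- short_config(seed = 21, n_chains = 2, burn_in = 200,
                      n_iterations = 600, thinning = 3)
  f1 <- fit_ph_model(sim, ph_variant("M3"), cfg)
  f2 <- fit_ph_model(sim, ph_variant("M3"), cfg)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$deviance, f2$deviance)
  f3 <- fit_ph_model(sim, ph_variant("M3"), short_config(seed = 22,
                     n_chains = 2, burn_in = 200, n_iterations = 600,
                     thinning = 3))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("retained draws respect parameter supports and store deviance", {
  sim <- simulate_ph_data(tiny_design(3), ph_params(), seed = 17)
  for (v in c("M3", "M4")) {
    fit <- fit_ph_model(sim, ph_variant(v), short_config(seed = 19,
                        n_chains = 1, burn_in = 300, n_iterations = 900))
    d <- pooled_draws(fit)
    expect_true(all(d[, "theta"] > 8 & d[, "theta"] < 22))
    expect_true(all(d[, "sigma_pH"] > 0))
    expect_true(all(d[, "sigma_pH0"] > 0))
    expect_true(all(is.finite(unlist(fit$deviance))))
    # stored deviance equals -2 x log likelihood recomputed from the draw
    i <- nrow(fit$draws[[1]])
    p <- phbayes:::params_from_draw(fit$draws[[1]][i, ], fit$batch_levels)
    expect_equal(fit$deviance[[1]][i], -2 * log_likelihood(sim, p),
                 tolerance = 1e-8)
  }
})

test_that("per-chain starting points are overdispersed and distinct", {
  sim <- simulate_ph_data(tiny_design(2), ph_params(), seed = 23)
  cfg <- mcmc_config(n_chains = 3, burn_in = 0, n_iterations = 10,
                     thinning = 1, seed = 5)
  fit <- fit_ph_model(sim, ph_variant("M3"), cfg)
  firsts <- vapply(fit$draws, function(d) d[1, "theta"], numeric(1))
  expect_gt(length(unique(firsts)), 1)
})

test_that("user-supplied initial values are honoured", {
  sim <- simulate_ph_data(tiny_design(2), ph_params(), seed = 25)
  inits <- list(list(theta = 10), list(theta = 20))
  cfg <- mcmc_config(n_chains = 2, burn_in = 0, n_iterations = 4,
                     thinning = 1, seed = 5, initial_values = inits)
  fit <- fit_ph_model(sim, ph_variant("M3"), cfg)
  # theta moves by small adapted steps from the supplied starts
  expect_lt(abs(fit$draws[[1]][1, "theta"] - 10), 2)
  expect_lt(abs(fit$draws[[2]][1, "theta"] - 20), 2)
})

test_that("invalid observations are rejected before sampling", {
  bad <- tibble::tibble(batch_id = "B01", lactate_pct = 0,
                        atmosphere = "CO2", day = 2, pH = 6.4)
  expect_error(fit_ph_model(bad, ph_variant("M1"), short_config()),
               "atmosphere")
})
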