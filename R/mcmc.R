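#' MCMC sampler configuration
#'
#' Defaults follow the original analysis: three independent chains, a 5000
#' iteration burn-in, 60,000 post-burn-in iterations per chain thinned every
#' 6 iterations, giving 10,000 retained draws per chain (30,000 pooled).
#'
#' @param n_chains Number of independent chains (>= 1).
#' @param burn_in Burn-in iterations discarded from each chain; proposal
#'   scales adapt only during this period.
#' @param n_iterations Post-burn-in iterations per chain; must be divisible
#'   by `thinning`.
#' @param thinning Keep every `thinning`-th post-burn-in iteration.
#' @param seed Integer seed; chain c uses a seed derived from `seed` and c.
#' @param initial_values `"auto"` (overdispersed draws from the priors, with
#'   uniform supports shrunk 10% away from their boundaries) or a list of
#'   per-chain named lists of starting values.
#'
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3, burn_in = 5000, n_iterations = 60000,
                        thinning = 6, seed = 1, initial_values = "auto") {
  stopifnot(n_chains >= 1, burn_in >= 0, n_iterations >= 1, thinning >= 1)
  if (n_iterations %% thinning != 0) {
    abort("`thinning` must divide `n_iterations`.")
  }
  if (!identical(initial_values, "auto")) {
    if (!is.list(initial_values) || length(initial_values) != n_chains) {
      abort("`initial_values` must be \"auto\" or a list with one entry per chain.")
    }
  }
  structure(
    list(
      n_chains = as.integer(n_chains), burn_in = as.integer(burn_in),
      n_iterations = as.integer(n_iterations), thinning = as.integer(thinning),
      seed = as.integer(seed), initial_values = initial_values
    ),
    class = "mcmc_config"
  )
}

TOP_PARAMS <- c("mu_pH0", "sigma_pH0", "sigma_pH", "lambda",
                "delta_Air", "delta_MAP1", "delta_MAP2", "n", "theta")

#' Fit an acidification model variant by MCMC
#'
#' Samples the posterior of the two-phase acidification model with an
#' adaptive Gaussian random-walk Metropolis-within-Gibbs sampler: each free
#' population-level parameter is updated in its own block per sweep
#' (standard deviations on the log scale with a Jacobian correction), and
#' each batch's latent initial pH is refreshed with a conjugate
#' normal-normal Gibbs draw. Proposal scales adapt towards an acceptance
#' rate of about 0.44 during burn-in only and are frozen afterwards.
#'
#' With an empty dataset the sampler targets the prior, which is useful for
#' prior-recovery checks. The observation-model deviance
#' `-2 * log_likelihood` is stored for every retained draw, feeding
#' [compute_dic()].
#'
#' @param data Observation table with columns `batch_id`, `lactate_pct`,
#'   `atmosphere`, `day`, `pH` (zero rows allowed).
#' @param variant A [ph_variant()].
#' @param config An [mcmc_config()].
#' @param fixed Optional named list pinning parameters at constant values
#'   (e.g. `list(sigma_pH = 0.15)`, or `pH0 =` a named vector to pin the
#'   latent batch values); pinned parameters are excluded from updating.
#'
#' @return An object of class `ph_fit` holding, per chain, a matrix of
#'   retained draws (all population-level parameters plus one `pH0[batch]`
#'   column per batch) and the per-draw deviance, along with acceptance
#'   rates, frozen proposal scales, the variant and the configuration.
#' @examples
#' sim <- simulate_ph_data(ph_design(n_batches = 3, sampling_days = c(2, 8, 15)),
#'                         ph_params(), seed = 1)
#' fit <- fit_ph_model(sim, ph_variant("M1"),
#'                     mcmc_config(n_chains = 2, burn_in = 200,
#'                                 n_iterations = 600, thinning = 3, seed = 1))
#' glance(fit)
#' @export
fit_ph_model <- function(data, variant = ph_variant("M3"),
                         config = mcmc_config(), fixed = NULL) {
  stopifnot(inherits(variant, "ph_variant"), inherits(config, "mcmc_config"))
  data <- validate_ph_data(tibble::as_tibble(data))
  obs <- prep_obs(data)

  free <- setdiff(free_param_names(variant), names(fixed))
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    init <- if (identical(config$initial_values, "auto")) NULL
            else config$initial_values[[ch]]
    chains[[ch]] <- run_chain(
      obs, variant, config, free, fixed,
      chain_seed = config$seed + 7919L * (ch - 1L),
      init = init
    )
  }

  structure(
    list(
      draws = purrr::map(chains, "draws"),
      deviance = purrr::map(chains, "deviance"),
      acceptance = purrr::map(chains, "acceptance"),
      scales_at_freeze = purrr::map(chains, "scales_at_freeze"),
      scales_final = purrr::map(chains, "scales_final"),
      variant = variant,
      config = config,
      free_params = free,
      batch_levels = obs$batch_levels,
      n_obs = obs$n_obs
    ),
    class = "ph_fit"
  )
}

#' @export
print.ph_fit <- function(x, ...) {
  cat(sprintf(
    "<ph_fit %s> %d chains x %d retained draws (%d pooled); %d observations, %d batches\n",
    x$variant$name, length(x$draws), nrow(x$draws[[1]]),
    length(x$draws) * nrow(x$draws[[1]]), x$n_obs, length(x$batch_levels)
  ))
  invisible(x)
}

#' Pooled posterior draws of a fit
#'
#' Row-binds the retained draws of all chains into one matrix (one column
#' per sampled quantity, including the latent per-batch initial pH values).
#'
#' @param fit A [fit_ph_model()] result.
#' @return A numeric matrix with named columns.
#' @export
pooled_draws <- function(fit) {
  do.call(rbind, fit$draws)
}

# One chain of the Metropolis-within-Gibbs sampler. obs comes from
# prep_obs(); free lists the population-level parameters to update.
run_chain <- function(obs, variant, config, free, fixed, chain_seed, init) {
  set.seed(chain_seed)
  pr <- variant$priors
  N <- obs$n_obs
  R <- length(obs$batch_levels)
  y <- obs$y; tt <- obs$t; lact <- obs$lact
  atm_idx <- obs$atm_idx; batch_idx <- obs$batch_idx

  batch_rows <- if (R > 0) split(seq_len(N), factor(batch_idx, levels = seq_len(R)))
                else list()
  batch_ysum <- vapply(batch_rows, function(i) sum(y[i]), numeric(1))
  batch_n <- vapply(batch_rows, length, numeric(1))
  atm_rows <- lapply(1:3, function(a) which(atm_idx == a))

  pH0_fixed <- "pH0" %in% names(fixed)

  draw_start <- function() {
    st <- list(
      mu_pH0 = prior_draw_start(pr$mu_pH0),
      sigma_pH0 = prior_draw_start(pr$sigma_pH0),
      sigma_pH = prior_draw_start(pr$sigma_pH),
      lambda = prior_draw_start(pr$lambda),
      delta_Air = prior_draw_start(pr$delta_Air),
      delta_MAP1 = prior_draw_start(pr$delta_MAP1),
      delta_MAP2 = prior_draw_start(pr$delta_MAP2),
      n = if (variant$n_fixed) variant$n_value else prior_draw_start(pr$n),
      theta = if (variant$theta_fixed) variant$theta_value
              else prior_draw_start(pr$theta)
    )
    # zero-lactate observations need n > 0 for a finite rate
    if (!variant$n_fixed && any(lact == 0) && st$n <= 0) st$n <- abs(st$n) + 0.1
    for (nm in intersect(names(fixed), TOP_PARAMS)) st[[nm]] <- fixed[[nm]]
    if (!is.null(init)) for (nm in intersect(names(init), TOP_PARAMS)) st[[nm]] <- init[[nm]]
    st$pH0 <-
      if (pH0_fixed) unname(fixed$pH0[obs$batch_levels])
      else if (!is.null(init) && !is.null(init$pH0)) unname(init$pH0[obs$batch_levels])
      else rnorm(R, st$mu_pH0, max(st$sigma_pH0, 1e-3))
    st
  }

  recache <- function(st) {
    deltas <- c(st$delta_Air, st$delta_MAP1, st$delta_MAP2)
    Lp <- lactate_power(lact, st$n)
    beta <- exp(st$lambda * Lp + deltas[atm_idx])
    mt <- pmin(tt, st$theta)
    drop <- beta * mt
    res <- y - (st$pH0[batch_idx] - drop)
    list(Lp = Lp, beta = beta, mt = mt, drop = drop, res = res,
         SSR = sum(res * res))
  }

  state_lp <- function(st, ca) {
    p <- ph_params(st$mu_pH0, st$sigma_pH0, st$sigma_pH, st$lambda,
                   st$delta_Air, st$delta_MAP1, st$delta_MAP2,
                   st$n, st$theta,
                   pH0 = setNames(st$pH0, obs$batch_levels))
    ll <- if (N == 0) 0 else
      -0.5 * N * log(2 * pi) - N * log(st$sigma_pH) - ca$SSR / (2 * st$sigma_pH^2)
    ll + log_prior(p, variant)
  }

  st <- NULL
  for (attempt in 1:100) {
    cand <- draw_start()
    if (any(!is.finite(unlist(cand)))) next
    ca <- recache(cand)
    if (is.finite(state_lp(cand, ca))) { st <- cand; break }
  }
  if (is.null(st)) {
    abort(paste0("Could not find a finite starting log-posterior after 100 ",
                 "attempts; check priors, fixed values (often `n` or `theta`) ",
                 "and the data."))
  }

  # unpack to scalars for the hot loop
  mu <- st$mu_pH0; sig0 <- st$sigma_pH0; sig <- st$sigma_pH
  lambda <- st$lambda; dl <- c(st$delta_Air, st$delta_MAP1, st$delta_MAP2)
  nval <- st$n; theta <- st$theta; pH0v <- st$pH0
  Lp <- ca$Lp; beta <- ca$beta; mt <- ca$mt; drop <- ca$drop
  res <- ca$res; SSR <- ca$SSR

  supp <- lapply(pr[c("lambda", "n", "theta")], prior_support)
  mu_m <- pr$mu_pH0$mean; mu_s <- pr$mu_pH0$sd
  hn0_s <- pr$sigma_pH0$sd; hn_s <- pr$sigma_pH$sd
  dsupp <- lapply(pr[c("delta_Air", "delta_MAP1", "delta_MAP2")], prior_support)

  upd <- intersect(free, c("lambda", "delta_Air", "delta_MAP1", "delta_MAP2",
                           "n", "theta", "sigma_pH", "mu_pH0", "sigma_pH0"))
  ls_scale <- setNames(rep(log(0.1), length(upd)), upd)
  ls_scale[names(ls_scale) %in% c("sigma_pH", "sigma_pH0")] <- log(0.3)
  n_prop <- setNames(rep(0L, length(upd)), upd)
  n_acc <- setNames(rep(0L, length(upd)), upd)

  burn <- config$burn_in; thin <- config$thinning
  n_iter <- config$n_iterations
  total <- burn + n_iter
  n_keep <- n_iter %/% thin
  col_names <- c(TOP_PARAMS,
                 if (R > 0) sprintf("pH0[%s]", obs$batch_levels))
  draws <- matrix(NA_real_, n_keep, length(col_names),
                  dimnames = list(NULL, col_names))
  deviance <- numeric(n_keep)
  scales_at_freeze <- NULL
  keep_i <- 0L

  do_lambda_like <- function(nm, iter) {
    # full-likelihood block for lambda, n, theta
    s <- exp(ls_scale[[nm]])
    cur <- switch(nm, lambda = lambda, n = nval, theta = theta)
    propv <- cur + rnorm(1, 0, s)
    sp <- supp[[nm]]
    alpha <- 0
    if (propv >= sp[1] && propv <= sp[2]) {
      if (nm == "lambda") {
        beta_p <- exp(propv * Lp + dl[atm_idx]); mt_p <- mt
        Lp_p <- Lp
      } else if (nm == "n") {
        Lp_p <- lact^propv
        zero <- lact == 0
        if (any(zero)) Lp_p[zero] <- if (propv > 0) 0 else NaN
        beta_p <- exp(lambda * Lp_p + dl[atm_idx]); mt_p <- mt
      } else {
        Lp_p <- Lp; beta_p <- beta; mt_p <- pmin(tt, propv)
      }
      drop_p <- beta_p * mt_p
      if (!anyNA(drop_p) && all(is.finite(drop_p))) {
        res_p <- y - (pH0v[batch_idx] - drop_p)
        SSR_p <- sum(res_p * res_p)
        logr <- (SSR - SSR_p) / (2 * sig^2)
        alpha <- if (is.finite(logr)) min(1, exp(logr)) else 0
        if (alpha > 0 && runif(1) < alpha) {
          if (nm == "lambda") lambda <<- propv
          else if (nm == "n") { nval <<- propv; Lp <<- Lp_p }
          else { theta <<- propv; mt <<- mt_p }
          beta <<- beta_p; drop <<- drop_p; res <<- res_p; SSR <<- SSR_p
          if (iter > burn) n_acc[nm] <<- n_acc[nm] + 1L
        }
      }
    }
    if (iter <= burn) {
      n_prop[nm] <<- n_prop[nm] + 1L
      ls_scale[nm] <<- ls_scale[nm] + (alpha - 0.44) / n_prop[nm]^0.6
    } else n_prop[nm] <<- n_prop[nm] + 1L
  }

  do_delta <- function(a, iter) {
    nm <- c("delta_Air", "delta_MAP1", "delta_MAP2")[a]
    s <- exp(ls_scale[[nm]])
    propv <- dl[a] + rnorm(1, 0, s)
    sp <- dsupp[[a]]
    alpha <- 0
    idx <- atm_rows[[a]]
    if (propv >= sp[1] && propv <= sp[2]) {
      if (length(idx) == 0) {
        alpha <- 1
        dl[a] <<- propv
        if (iter > burn) n_acc[nm] <<- n_acc[nm] + 1L
      } else {
        fac <- exp(propv - dl[a])
        drop_s <- drop[idx] * fac
        res_s <- y[idx] - (pH0v[batch_idx[idx]] - drop_s)
        dSSR <- sum(res_s * res_s) - sum(res[idx]^2)
        logr <- -dSSR / (2 * sig^2)
        alpha <- if (is.finite(logr)) min(1, exp(logr)) else 0
        if (alpha > 0 && runif(1) < alpha) {
          dl[a] <<- propv
          beta[idx] <<- beta[idx] * fac
          drop[idx] <<- drop_s
          res[idx] <<- res_s
          SSR <<- SSR + dSSR
          if (iter > burn) n_acc[nm] <<- n_acc[nm] + 1L
        }
      }
    }
    if (iter <= burn) {
      n_prop[nm] <<- n_prop[nm] + 1L
      ls_scale[nm] <<- ls_scale[nm] + (alpha - 0.44) / n_prop[nm]^0.6
    } else n_prop[nm] <<- n_prop[nm] + 1L
  }

  half_norm_lp <- function(x, s) -x * x / (2 * s * s) # kernel; constants cancel

  do_sigma <- function(iter) {
    nm <- "sigma_pH"
    s <- exp(ls_scale[[nm]])
    lsig_p <- log(sig) + rnorm(1, 0, s)
    sig_p <- exp(lsig_p)
    logr <- -N * (lsig_p - log(sig)) - SSR / 2 * (1 / sig_p^2 - 1 / sig^2) +
      half_norm_lp(sig_p, hn_s) - half_norm_lp(sig, hn_s) +
      (lsig_p - log(sig)) # Jacobian of the log transform
    alpha <- if (is.finite(logr)) min(1, exp(logr)) else 0
    if (alpha > 0 && runif(1) < alpha) {
      sig <<- sig_p
      if (iter > burn) n_acc[nm] <<- n_acc[nm] + 1L
    }
    if (iter <= burn) {
      n_prop[nm] <<- n_prop[nm] + 1L
      ls_scale[nm] <<- ls_scale[nm] + (alpha - 0.44) / n_prop[nm]^0.6
    } else n_prop[nm] <<- n_prop[nm] + 1L
  }

  do_mu <- function(iter) {
    nm <- "mu_pH0"
    s <- exp(ls_scale[[nm]])
    mu_p <- mu + rnorm(1, 0, s)
    hier <- if (R > 0) (sum((pH0v - mu)^2) - sum((pH0v - mu_p)^2)) / (2 * sig0^2)
            else 0
    logr <- hier +
      ((mu - mu_m)^2 - (mu_p - mu_m)^2) / (2 * mu_s^2)
    alpha <- if (is.finite(logr)) min(1, exp(logr)) else 0
    if (alpha > 0 && runif(1) < alpha) {
      mu <<- mu_p
      if (iter > burn) n_acc[nm] <<- n_acc[nm] + 1L
    }
    if (iter <= burn) {
      n_prop[nm] <<- n_prop[nm] + 1L
      ls_scale[nm] <<- ls_scale[nm] + (alpha - 0.44) / n_prop[nm]^0.6
    } else n_prop[nm] <<- n_prop[nm] + 1L
  }

  do_sigma0 <- function(iter) {
    nm <- "sigma_pH0"
    s <- exp(ls_scale[[nm]])
    l_p <- log(sig0) + rnorm(1, 0, s)
    sig0_p <- exp(l_p)
    hier <- if (R > 0) {
      ssq <- sum((pH0v - mu)^2)
      -R * (l_p - log(sig0)) - ssq / 2 * (1 / sig0_p^2 - 1 / sig0^2)
    } else 0
    logr <- hier + half_norm_lp(sig0_p, hn0_s) - half_norm_lp(sig0, hn0_s) +
      (l_p - log(sig0))
    alpha <- if (is.finite(logr)) min(1, exp(logr)) else 0
    if (alpha > 0 && runif(1) < alpha) {
      sig0 <<- sig0_p
      if (iter > burn) n_acc[nm] <<- n_acc[nm] + 1L
    }
    if (iter <= burn) {
      n_prop[nm] <<- n_prop[nm] + 1L
      ls_scale[nm] <<- ls_scale[nm] + (alpha - 0.44) / n_prop[nm]^0.6
    } else n_prop[nm] <<- n_prop[nm] + 1L
  }

  gibbs_pH0 <- function() {
    # conjugate normal-normal draw per batch: y_i + drop_i = pH0_r + noise
    for (r in seq_len(R)) {
      idx <- batch_rows[[r]]
      nr <- batch_n[r]
      prec <- nr / sig^2 + 1 / sig0^2
      m <- (if (nr > 0) (batch_ysum[r] + sum(drop[idx])) / sig^2 else 0)
      m <- (m + mu / sig0^2) / prec
      new_val <- rnorm(1, m, sqrt(1 / prec))
      if (nr > 0) {
        res_new <- res[idx] + (pH0v[r] - new_val)
        SSR <<- SSR + sum(res_new * res_new) - sum(res[idx]^2)
        res[idx] <<- res_new
      }
      pH0v[r] <<- new_val
    }
  }

  has <- function(nm) nm %in% upd

  for (iter in seq_len(total)) {
    if (has("lambda")) do_lambda_like("lambda", iter)
    if (has("delta_Air")) do_delta(1L, iter)
    if (has("delta_MAP1")) do_delta(2L, iter)
    if (has("delta_MAP2")) do_delta(3L, iter)
    if (has("n")) do_lambda_like("n", iter)
    if (has("theta")) do_lambda_like("theta", iter)
    if (has("sigma_pH")) do_sigma(iter)
    if (has("mu_pH0")) do_mu(iter)
    if (has("sigma_pH0")) do_sigma0(iter)
    if (R > 0 && !pH0_fixed) gibbs_pH0()

    if (iter == burn) scales_at_freeze <- exp(ls_scale)
    if (iter > burn && (iter - burn) %% thin == 0L) {
      keep_i <- keep_i + 1L
      draws[keep_i, 1:9] <- c(mu, sig0, sig, lambda, dl[1], dl[2], dl[3],
                              nval, theta)
      if (R > 0) draws[keep_i, 9L + seq_len(R)] <- pH0v
      deviance[keep_i] <- if (N == 0) 0 else
        N * log(2 * pi) + 2 * N * log(sig) + SSR / sig^2
    }
  }

  list(
    draws = draws,
    deviance = deviance,
    acceptance = if (length(upd) > 0) n_acc / (total - burn) else setNames(numeric(0), character(0)),
    scales_at_freeze = if (is.null(scales_at_freeze)) exp(ls_scale) else scales_at_freeze,
    scales_final = exp(ls_scale)
  )
}
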