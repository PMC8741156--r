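# DE-MCMC: crossover, migration, diagnostics, conjugate recovery

test_that("config invariants are enforced", {
  expect_error(de_config(n_iter = 100, burn_in = 100), "burn_in")
  expect_error(de_config(n_iter = 100, burn_in = 50,
                         migration_window = c(50, 200)), "window")
})

test_that("a degenerate move (gamma = 0, no jitter) leaves states unchanged
           and is always accepted", {
  set.seed(20)
  cfg <- de_config(n_chains = 6, n_iter = 10, burn_in = 1,
                   migration_interval = 0, gamma_scale = 0, jitter = 0,
                   mode_jump_prob = 0)
  states <- matrix(rnorm(6), 6, 1)
  lp <- -states[, 1]^2 / 2
  out <- driftslope:::de_crossover(states, lp,
                                   1, function(S) -S[, 1]^2 / 2, cfg)
  expect_identical(out$states, states)
  expect_true(all(out$accept))
})

test_that("the sampler recovers the moments of a standard normal", {
  cfg <- de_config(n_chains = 15, n_iter = 5000, burn_in = 1000,
                   migration_interval = 0, seed = 3)
  fit <- de_sample(function(x) dnorm(x, log = TRUE), 1, cfg)
  draws <- as.numeric(posterior_matrix(fit))
  n_eff_floor <- length(draws) / 60  # conservative for autocorrelation
  expect_lt(abs(mean(draws)), 3 / sqrt(n_eff_floor))
  expect_lt(abs(var(draws) - 1), 0.05)
  expect_gt(fit$accept_rate, 0)
  expect_lt(fit$accept_rate, 1)
})

test_that("fixed seeds give bit-identical chains", {
  cfg <- de_config(n_chains = 6, n_iter = 200, burn_in = 50,
                   migration_interval = 10, migration_window = c(20, 150),
                   seed = 5)
  f1 <- de_sample(function(x) -sum(x^2) / 2, 2, cfg)
  f2 <- de_sample(function(x) -sum(x^2) / 2, 2, cfg)
  expect_identical(f1$draws, f2$draws)
})

test_that("disabling migration reproduces trajectories up to the window
           start", {
  tgt <- function(x) -sum(x^2) / 2
  cfg_m <- de_config(n_chains = 6, n_iter = 120, burn_in = 10,
                     migration_interval = 14, migration_window = c(50, 110),
                     seed = 6)
  cfg_0 <- de_config(n_chains = 6, n_iter = 120, burn_in = 10,
                     migration_interval = 0, seed = 6)
  f_m <- de_sample(tgt, 1, cfg_m)
  f_0 <- de_sample(tgt, 1, cfg_0)
  expect_identical(f_m$draws[1:49, , ], f_0$draws[1:49, , ])
})

test_that("migration proposals between identical states leave them
           unchanged", {
  set.seed(7)
  states <- matrix(rep(1.5, 8), 8, 1)
  lp <- rep(-1.125, 8)
  out <- driftslope:::de_migrate(states, lp)
  expect_identical(out$states, states)
  expect_true(all(out$accept))
})

test_that("migration lets chains populate both modes of a bimodal target", {
  lmix <- function(x) {
    log(0.5 * dnorm(x, -4, 0.3) + 0.5 * dnorm(x, 4, 0.3))
  }
  cfg <- de_config(n_chains = 15, n_iter = 3000, burn_in = 1000,
                   migration_interval = 14, migration_window = c(100, 2900),
                   seed = 8)
  init <- matrix(rnorm(15, c(rep(-4, 10), rep(4, 5)), 0.3), 15, 1)
  fit <- de_sample(lmix, 1, cfg, init = init)
  draws <- as.numeric(posterior_matrix(fit))
  expect_gt(mean(draws > 0), 0.2)
  expect_gt(mean(draws < 0), 0.2)
})

test_that("a chain started at stationarity stays there", {
  cfg <- de_config(n_chains = 10, n_iter = 2000, burn_in = 1,
                   migration_interval = 0, seed = 9)
  set.seed(10)
  init <- matrix(rnorm(10), 10, 1)  # exact draws from the target
  fit <- de_sample(function(x) dnorm(x, log = TRUE), 1, cfg, init = init)
  thin <- as.numeric(fit$draws[seq(10, 2000, by = 40), , 1])
  expect_gt(suppressWarnings(stats::ks.test(thin, "pnorm")$p.value), 0.01)
})

test_that("Gelman-Rubin behaves at its reference points", {
  one <- rnorm(500)
  same <- array(rep(one, 3), c(500, 3, 1))
  expect_identical(unname(gelman_rubin(same)), 1)

  set.seed(11)
  iid <- array(rnorm(2000 * 4), c(2000, 4, 1))
  expect_lt(gelman_rubin(iid), 1.05)

  apart <- array(rnorm(500 * 3, rep(c(-2, 0, 2), each = 500)), c(500, 3, 1))
  expect_gt(gelman_rubin(apart), 1.5)

  expect_error(gelman_rubin(array(rnorm(100), c(100, 1, 1))), "2 chains")
})

test_that("the blocked sampler recovers a conjugate normal hierarchy", {
  # y_pj ~ N(theta_p, 1), theta_p ~ N(mu, tau^2), mu ~ N(0, 10^2);
  # the marginal posterior of mu is available in closed form
  set.seed(12)
  P <- 6; J <- 8; tau <- 0.5
  theta_true <- rnorm(P, 1, tau)
  y <- matrix(rnorm(P * J, rep(theta_true, each = J), 1), J, P)
  ybar <- colMeans(y)
  v_marg <- tau^2 + 1 / J
  post_prec <- P / v_marg + 1 / 100
  mu_post_mean <- sum(ybar / v_marg) / post_prec
  mu_post_sd <- sqrt(1 / post_prec)

  lt <- function(par) {
    th <- par[1:P]; mu <- par[P + 1]
    sum(dnorm(ybar, th, 1 / sqrt(J), log = TRUE)) +
      sum(dnorm(th, mu, tau, log = TRUE)) + dnorm(mu, 0, 10, log = TRUE)
  }
  cfg <- de_config(n_chains = 15, n_iter = 3000, burn_in = 1000,
                   migration_interval = 14, migration_window = c(100, 1000),
                   seed = 13)
  fit <- de_sample(lt, P + 1, cfg,
                   blocks = c(lapply(seq_len(P), identity), list(P + 1)))
  mu_draws <- posterior_matrix(fit)[, P + 1]
  n_eff_floor <- length(mu_draws) / 60
  mcse <- mu_post_sd / sqrt(n_eff_floor)
  expect_lt(abs(mean(mu_draws) - mu_post_mean), 3 * mcse)
  expect_lt(abs(sd(mu_draws) - mu_post_sd), 0.25 * mu_post_sd)
})

test_that("stored hierarchical draws always respect parameter supports", {
  sim <- tiny_sim(n = 2, seed = 17)
  flt <- filter_trials(sim$trials)
  cfg <- de_config(n_chains = 6, n_iter = 120, burn_in = 20,
                   migration_interval = 7, migration_window = c(10, 100),
                   seed = 17)
  fit <- fit_hddm(flt$trials, config = cfg)
  pm <- posterior_matrix(fit)
  expect_true(all(pm[, grep("^a\\[", colnames(pm))] > 0))
  zc <- pm[, grep("^z\\[", colnames(pm))]
  expect_true(all(zc > 0 & zc < 1))
  expect_true(all(pm[, grep("^ter\\[", colnames(pm))] >= 0))
  expect_true(all(pm[, grep("^sigma_", colnames(pm))] > 0))
})
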