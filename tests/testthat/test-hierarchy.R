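# trial filter, subject-level densities, joint log posterior

# independent scalar-density oracle for the hyperprior (default priors)
hyperprior_sum_oracle <- function(hy) {
  pri <- default_priors()
  tn <- function(x, m, s, lo, hi) {
    dnorm(x, m, s, log = TRUE) - log(pnorm(hi, m, s) - pnorm(lo, m, s))
  }
  tot <- 0
  for (i in seq_len(nrow(hy))) {
    row <- pri[pri$param == hy$param[i] & pri$hyper == "mu", ]
    tot <- tot + if (row$dist == "tnorm") {
      tn(hy$mu[i], row$p1, row$p2, row$lower, row$upper)
    } else dnorm(hy$mu[i], row$p1, row$p2, log = TRUE)
    tot <- tot + dgamma(hy$sigma[i], 1, 1, log = TRUE)
    tot <- tot + dnorm(hy$delta[i], 0, 0.01, log = TRUE)
  }
  tot
}

test_that("the RT filter removes fast responses and catch trials but keeps
           timeouts", {
  base <- tibble::tibble(participant_id = "p001", group = "typical",
                         task = "motion_coherence", difficulty = "easy",
                         direction = "right", response = "right",
                         rt_s = c(0.15, 0.5, NA, 0.6),
                         timeout = c(FALSE, FALSE, TRUE, FALSE),
                         catch = c(FALSE, FALSE, FALSE, TRUE))
  flt <- filter_trials(base)
  expect_equal(nrow(flt$trials), 2L)
  expect_equal(flt$report$n_fast_removed, 1L)
  expect_equal(flt$report$n_catch_removed, 1L)
  expect_equal(flt$report$n_timeout_retained, 1L)

  all_to <- dplyr::mutate(base[3, ], rt_s = NA_real_)
  expect_equal(filter_trials(all_to)$report$n_fast_removed, 0L)
})

test_that("exclusion fraction tracks an injected contamination rate", {
  g <- generator_config(fast_guess_rate = 0.05)
  d <- study_design(n_per_group = 6, tasks = "motion_coherence")
  sim <- simulate_behaviour(d, g, seed = 13)
  flt <- filter_trials(sim$trials)
  # ~2/3 of uniform [0, 0.3] guesses fall under the 200 ms floor
  expected <- 0.05 * 2 / 3
  frac <- sum(flt$report$n_fast_removed) /
    sum(flt$report$n_total - flt$report$n_catch_removed)
  se <- sqrt(expected * (1 - expected) / sum(flt$report$n_total))
  expect_lt(abs(frac - expected), 3 * se + 0.005)
})

test_that("subject density matches an independently coded sum of scalar
           log densities", {
  hy <- tibble::tibble(param = c("a", "z", "ter", "v.diff", "v.mean"),
                       mu = c(0.15, 0.5, 0.3, 0.1, 0.2),
                       sigma = c(0.03, 0.05, 0.05, 0.05, 0.05),
                       delta = c(0.01, -0.005, 0, 0.02, -0.02))
  th <- c(a = 0.14, z = 0.52, ter = 0.31, v.diff = 0.12, v.mean = 0.17)
  got <- subject_logdens(th, hy, "dyslexia")
  # oracle: scalar truncated-normal and normal log densities
  tn <- function(x, m, s, lo, hi) {
    dnorm(x, m, s, log = TRUE) - log(pnorm(hi, m, s) - pnorm(lo, m, s))
  }
  want <- tn(0.14, 0.15 + 0.01, 0.03, 0, Inf) +
    tn(0.52, 0.5 - 0.005, 0.05, 0, 1) +
    tn(0.31, 0.3, 0.05, 0, Inf) +
    dnorm(0.12, 0.1 + 0.02, 0.05, log = TRUE) +
    dnorm(0.17, 0.2 - 0.02, 0.05, log = TRUE)
  expect_equal(got, want, tolerance = 1e-12)

  # with all deltas zero the density is label-symmetric
  hy0 <- dplyr::mutate(hy, delta = 0)
  expect_equal(subject_logdens(th, hy0, "dyslexia"),
               subject_logdens(th, hy0, "typical"))
  # outside the support
  expect_identical(subject_logdens(replace(th, 1, -0.1), hy, "typical"),
                   -Inf)
})

test_that("the log posterior is additive and matches its component sum", {
  sim <- tiny_sim(n = 1, seed = 14)
  flt <- filter_trials(sim$trials)
  theta <- dplyr::select(sim$subjects, participant_id, group, a, z, ter,
                         v.diff, v.mean)
  hy <- tibble::tibble(param = c("a", "z", "ter", "v.diff", "v.mean"),
                       mu = c(0.15, 0.5, 0.3, 0.15, 0.2),
                       sigma = c(0.03, 0.05, 0.05, 0.05, 0.05),
                       delta = rep(0, 5))
  lp <- log_posterior(theta, hy, flt$trials)
  expect_true(is.finite(lp))

  # component-sum oracle
  want <- hyperprior_sum_oracle(hy) +
    sum(vapply(theta$participant_id, function(id) {
      row <- theta[theta$participant_id == id, ]
      tr <- flt$trials[flt$trials$participant_id == id, ]
      prep <- driftslope:::prepare_trials(tr)
      ll <- wfpt_loglik(
        dplyr::select(prep, difficulty, dir_sign, response, rt),
        c(a = row$a, z_rel = row$z, ter = row$ter, v_mean = row$v.mean,
          v_diff = row$v.diff))
      ll + subject_logdens(c(a = row$a, z = row$z, ter = row$ter,
                             v.diff = row$v.diff, v.mean = row$v.mean),
                           hy, row$group)
    }, numeric(1)))
  expect_equal(lp, want, tolerance = 1e-8)

  # duplicating one trial shifts the value by exactly that trial's loglik
  tr1 <- flt$trials[1, ]
  lp2 <- log_posterior(theta, hy, dplyr::bind_rows(flt$trials, tr1))
  prep1 <- driftslope:::prepare_trials(tr1)
  row <- theta[theta$participant_id == tr1$participant_id, ]
  ll1 <- wfpt_loglik(prep1, c(a = row$a, z_rel = row$z, ter = row$ter,
                              v_mean = row$v.mean, v_diff = row$v.diff))
  expect_equal(lp2 - lp, ll1, tolerance = 1e-8)

  # invariance to participant reordering (2 participants)
  sim2 <- tiny_sim(n = 2, seed = 15)
  flt2 <- filter_trials(sim2$trials)
  th2 <- dplyr::select(sim2$subjects, participant_id, group, a, z, ter,
                       v.diff, v.mean)
  expect_equal(log_posterior(th2, hy, flt2$trials),
               log_posterior(th2[rev(seq_len(nrow(th2))), ], hy,
                             flt2$trials),
               tolerance = 1e-10)

  # empty data: hyperprior + subject-level terms only
  lp0 <- log_posterior(theta, hy, flt$trials[0, ])
  want0 <- hyperprior_sum_oracle(hy) +
    sum(vapply(seq_len(nrow(theta)), function(i)
      subject_logdens(c(a = theta$a[i], z = theta$z[i], ter = theta$ter[i],
                        v.diff = theta$v.diff[i],
                        v.mean = theta$v.mean[i]),
                      hy, theta$group[i]), numeric(1)))
  expect_equal(lp0, want0, tolerance = 1e-10)
})

test_that("prior-predictive subject draws respect the type invariants", {
  set.seed(16)
  pri <- default_priors()
  for (i in 1:200) {
    mu <- c(driftslope:::prior_draw(as.list(pri[pri$param == "a" &
                                                  pri$hyper == "mu", ])),
            driftslope:::prior_draw(as.list(pri[pri$param == "z" &
                                                  pri$hyper == "mu", ])))
    expect_gt(mu[1], 0)
    expect_true(mu[2] > 0 && mu[2] < 1)
  }
})

test_that("five subject parameters with three hyperparameters each", {
  pri <- default_priors()
  expect_equal(length(unique(pri$param)), 5L)
  expect_equal(nrow(pri), 15L)
  expect_true(all(table(pri$param) == 3L))
})
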