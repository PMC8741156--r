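# Wiener first-passage core: density, CDF, choice probabilities, simulator,
# trial likelihood

test_that("density is zero at or below the non-decision time", {
  p <- default_params()
  expect_equal(wfpt_density(c(0.1, 0.3), "upper", p), c(0, 0))
  expect_gt(wfpt_density(0.35, "upper", p), 0)
})

test_that("unbiased zero-drift process is symmetric across bounds", {
  p <- default_params(v = 0)
  tt <- seq(0.31, 2, by = 0.05)
  expect_equal(wfpt_density(tt, "upper", p), wfpt_density(tt, "lower", p),
               tolerance = 1e-12)
  expect_equal(wfpt_choice_prob("upper", p), 0.5, tolerance = 1e-9)
})

test_that("choice probability matches the closed-form absorption formula", {
  for (v in c(-0.3, 0.05, 0.2)) {
    for (zr in c(0.3, 0.5, 0.7)) {
      p <- default_params(v = v, z_rel = zr)
      closed <- expm1(-2 * v * p$a * zr / p$s^2) / expm1(-2 * v * p$a / p$s^2)
      expect_equal(wfpt_choice_prob("upper", p), closed, tolerance = 1e-10)
    }
  }
})

test_that("densities over both bounds integrate to one", {
  for (p in list(default_params(),
                 default_params(a = 0.15, v = -0.1, z_rel = 0.4),
                 default_params(a = 0.08, v = 0.5, ter = 0.2))) {
    up <- integrate(function(t) wfpt_density(t, "upper", p), p$ter, 90,
                    rel.tol = 1e-9)$value
    lo <- integrate(function(t) wfpt_density(t, "lower", p), p$ter, 90,
                    rel.tol = 1e-9)$value
    expect_equal(up + lo, 1, tolerance = 1e-5)
    expect_equal(up, wfpt_choice_prob("upper", p), tolerance = 1e-5)
  }
})

test_that("CDF is consistent with the density and the survivor function", {
  p <- default_params(v = 0.15, z_rel = 0.45)
  tt <- seq(0.32, 2.5, by = 0.07)
  for (bound in c("upper", "lower")) {
    num <- vapply(tt, function(t)
      integrate(function(u) wfpt_density(u, bound, p), p$ter, t,
                rel.tol = 1e-10)$value, numeric(1))
    expect_equal(wfpt_cdf(tt, bound, p), num, tolerance = 1e-4)
  }
  sv <- wfpt_survivor(tt, p)
  expect_equal(sv, 1 - wfpt_cdf(tt, "upper", p) - wfpt_cdf(tt, "lower", p),
               tolerance = 1e-10)
  expect_true(all(diff(sv) <= 1e-12))       # monotone non-increasing
  expect_equal(wfpt_survivor(p$ter, p), 1)  # nothing has terminated yet
  expect_lt(wfpt_survivor(60, p), 1e-6)     # completeness
})

test_that("RT distributions are invariant to consistent evidence rescaling", {
  p1 <- default_params(a = 0.1, v = 0.2, s = 0.1)
  p2 <- default_params(a = 1.0, v = 2.0, s = 1.0)
  tt <- seq(0.31, 2, by = 0.1)
  expect_equal(wfpt_density(tt, "upper", p1), wfpt_density(tt, "upper", p2),
               tolerance = 1e-9)
  expect_equal(wfpt_choice_prob("lower", p1), wfpt_choice_prob("lower", p2),
               tolerance = 1e-12)
})

test_that("simulator agrees with the analytic distribution", {
  p <- default_params(v = 0.2)
  set.seed(41)
  sim <- wfpt_simulate(1e5, p, deadline = 30)
  # choice probability within 3 binomial SEs
  pu <- wfpt_choice_prob("upper", p)
  se <- sqrt(pu * (1 - pu) / nrow(sim))
  expect_lt(abs(mean(sim$response == "upper") - pu), 3 * se)
  # Kolmogorov distance of the pooled RT distribution
  tg <- seq(0.3, 5, by = 0.005)
  f_all <- wfpt_cdf(tg, "upper", p) + wfpt_cdf(tg, "lower", p)
  emp <- ecdf(sim$rt)
  expect_lt(max(abs(emp(tg) - f_all)), 0.01)
  # mean RT against quadrature of the density
  m_num <- integrate(function(t) t * (wfpt_density(t, "upper", p) +
                                        wfpt_density(t, "lower", p)),
                     p$ter, 60, rel.tol = 1e-9)$value
  se_m <- sd(sim$rt) / sqrt(nrow(sim))
  expect_lt(abs(mean(sim$rt) - m_num), 3 * se_m)
})

test_that("extreme drift hits the upper bound at once", {
  p <- default_params(v = 1000)
  set.seed(2)
  sim <- wfpt_simulate(200, p)
  expect_true(all(sim$response == "upper"))
  expect_lt(max(sim$rt), p$ter + 0.01)
})

test_that("trial log-likelihood handles responses, timeouts and the support
           boundary", {
  sub <- c(a = 0.1, z_rel = 0.5, ter = 0.3, v_mean = 0.2, v_diff = 0.1)
  tr <- tibble::tibble(difficulty = c(1L, 2L), dir_sign = c(1, -1),
                       response = c(1, 0), rt = c(0.6, 0.8))
  ll <- wfpt_loglik(tr, sub)
  # against the density functions directly (stimulus-coded drift)
  d1 <- wfpt_density(0.6, "upper", default_params(v = 0.25))
  d2 <- wfpt_density(0.8, "lower", default_params(v = -0.15))
  expect_equal(ll, log(d1) + log(d2), tolerance = 1e-10)

  # a timeout under a huge boundary has survivor 1, contribution log(1) = 0
  tr_to <- tibble::tibble(difficulty = 1L, dir_sign = 1,
                          response = NA_real_, rt = NA_real_)
  expect_equal(wfpt_loglik(tr_to, c(a = 50, z_rel = 0.5, ter = 0.3,
                                    v_mean = 0.2, v_diff = 0)), 0,
               tolerance = 1e-9)
  # generic timeout contribution equals log survivor at the deadline
  expect_equal(wfpt_loglik(tr_to, sub),
               log(wfpt_survivor(2.5, default_params(v = 0.25))),
               tolerance = 1e-8)

  # response faster than ter is outside the support: penalised, not -Inf
  tr_fast <- tibble::tibble(difficulty = 1L, dir_sign = 1, response = 1,
                            rt = 0.25)
  expect_equal(wfpt_loglik(tr_fast, sub), -1e10)
  expect_error(wfpt_loglik(dplyr::mutate(tr_fast, rt = -0.1), sub),
               "rt > 0")
})

test_that("summed log-likelihood peaks near the generating drift", {
  set.seed(7)
  p <- default_params(v = 0.2)
  sim <- wfpt_simulate(5000, p)
  tr <- tibble::tibble(difficulty = 1L, dir_sign = 1,
                       response = ifelse(sim$timeout, NA_real_,
                                         as.numeric(sim$response == "upper")),
                       rt = sim$rt)
  grid <- seq(0.05, 0.35, by = 0.025)
  prof <- vapply(grid, function(v)
    wfpt_loglik(tr, c(a = 0.1, z_rel = 0.5, ter = 0.3, v_mean = v,
                      v_diff = 0)), numeric(1))
  expect_lt(abs(grid[which.max(prof)] - 0.2), 0.03)
})
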