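#' Hyperprior specification
#'
#' Priors on the group-level hyperparameters of the hierarchical diffusion
#' model. Each of the five subject-level parameters (`a`, `z`, `ter`,
#' `v.diff`, `v.mean`) has three hyperparameters: a population mean `mu`, a
#' population SD `sigma`, and a half-difference between groups `delta`
#' (group means are `mu + delta` for the dyslexia group and `mu - delta`
#' for the typical group).
#'
#' Defaults: `mu_a ~ N+(0.2, 0.2)`, `mu_z ~ TN[0,1](0.5, 0.2)`,
#' `mu_ter ~ N+(0.3, 0.3)`, `mu_v.diff ~ N(0, 0.1)`,
#' `mu_v.mean ~ N(0.3, 0.3)`, every `sigma ~ Gamma(1, 1)` (shape/rate), and
#' every `delta ~ N(0, 0.01)`. The second argument of each (truncated)
#' normal is a standard deviation; both that reading and the Gamma
#' shape/rate convention can be overridden by editing the returned object.
#' The `delta` prior is deliberately narrow ("moderately informative"): it
#' is the Savage-Dickey numerator's reference density, so Bayes factors are
#' sensitive to its scale.
#'
#' @param delta_sd SD of every `delta` prior (default 0.01).
#' @return A tibble of class `prior_spec` with one row per hyperparameter:
#'   `param`, `hyper` (mu/sigma/delta), `dist` (`norm`, `tnorm`, `gamma`),
#'   `p1`, `p2` (mean/SD or shape/rate), `lower`, `upper`.
#' @export
default_priors <- function(delta_sd = 0.01) {
  pn <- c("a", "z", "ter", "v.diff", "v.mean")
  mu <- tibble::tibble(
    param = pn, hyper = "mu",
    dist = c("tnorm", "tnorm", "tnorm", "norm", "norm"),
    p1 = c(0.2, 0.5, 0.3, 0, 0.3),
    p2 = c(0.2, 0.2, 0.3, 0.1, 0.3),
    lower = c(0, 0, 0, -Inf, -Inf),
    upper = c(Inf, 1, Inf, Inf, Inf))
  sg <- tibble::tibble(param = pn, hyper = "sigma", dist = "gamma",
                       p1 = 1, p2 = 1, lower = 0, upper = Inf)
  dl <- tibble::tibble(param = pn, hyper = "delta", dist = "norm",
                       p1 = 0, p2 = delta_sd, lower = -Inf, upper = Inf)
  out <- dplyr::bind_rows(mu, sg, dl)
  class(out) <- c("prior_spec", class(out))
  out
}

#' EEG-side hyperpriors for the joint model
#'
#' Priors for the population distribution of the EEG slope measures in the
#' joint model: `mu_EEG.mean ~ N(0, 1)`, `mu_EEG.diff ~ N(0, 0.5)`,
#' `sigma ~ Gamma(1, 1)`, `delta ~ N(0, 0.01)`, and the drift-EEG
#' correlation `rho ~ U(-1, 1)`.
#'
#' @inheritParams default_priors
#' @return A `prior_spec` tibble over parameters `EEG.diff`, `EEG.mean`
#'   (hyper mu/sigma/delta) and `rho`.
#' @export
default_eeg_priors <- function(delta_sd = 0.01) {
  pn <- c("EEG.diff", "EEG.mean")
  out <- dplyr::bind_rows(
    tibble::tibble(param = pn, hyper = "mu", dist = "norm",
                   p1 = 0, p2 = c(0.5, 1), lower = -Inf, upper = Inf),
    tibble::tibble(param = pn, hyper = "sigma", dist = "gamma",
                   p1 = 1, p2 = 1, lower = 0, upper = Inf),
    tibble::tibble(param = pn, hyper = "delta", dist = "norm",
                   p1 = 0, p2 = delta_sd, lower = -Inf, upper = Inf),
    tibble::tibble(param = "rho", hyper = "rho", dist = "unif",
                   p1 = -1, p2 = 1, lower = -1, upper = 1))
  class(out) <- c("prior_spec", class(out))
  out
}

# log density of one prior row evaluated at x (vectorised over x)
prior_logdens <- function(row, x) {
  switch(row$dist,
         norm = dnorm(x, row$p1, row$p2, log = TRUE),
         tnorm = dtnorm(x, row$p1, row$p2, row$lower, row$upper, log = TRUE),
         gamma = dgamma(x, shape = row$p1, rate = row$p2, log = TRUE),
         unif = dunif(x, row$p1, row$p2, log = TRUE),
         stop("unknown prior family: ", row$dist))
}

# one draw per prior row
prior_draw <- function(row, n = 1) {
  switch(row$dist,
         norm = rnorm(n, row$p1, row$p2),
         tnorm = rtnorm1(rep(row$p1, n), row$p2, row$lower, row$upper),
         gamma = rgamma(n, shape = row$p1, rate = row$p2),
         unif = runif(n, row$p1, row$p2),
         stop("unknown prior family: ", row$dist))
}

#' Prior density at zero for a group-difference parameter
#'
#' Convenience accessor used by the Savage-Dickey ratio: the prior density
#' at `delta = 0` (or `rho = 0`).
#'
#' @param priors A `prior_spec` tibble.
#' @param param Parameter name (e.g. `"v.mean"`, `"rho"`).
#' @param hyper Hyperparameter (default `"delta"`).
#' @return The prior density at zero (not logged).
#' @export
prior_density_at_zero <- function(priors, param, hyper = "delta") {
  row <- priors[priors$param == param & priors$hyper == hyper, ]
  if (nrow(row) != 1) stop("no unique prior for ", param, "/", hyper,
                           call. = FALSE)
  exp(prior_logdens(as.list(row), 0))
}

# truncated-normal log density with normalisation constant.
# The truncation mass is computed in log space: the naive
# pnorm(upper) - pnorm(lower) underflows to 0 when (mu, sd) push the
# interval into a far tail, which would turn the log density into +Inf
# and hand MCMC an artificial mode.
dtnorm <- function(x, mean, sd, lower, upper, log = FALSE) {
  if (!is.finite(upper)) {
    lz <- pnorm(lower, mean, sd, lower.tail = FALSE, log.p = TRUE)
  } else if (!is.finite(lower)) {
    lz <- pnorm(upper, mean, sd, log.p = TRUE)
  } else {
    mid <- (lower + upper) / 2
    la_up <- pnorm(lower, mean, sd, lower.tail = FALSE, log.p = TRUE)
    lb_up <- pnorm(upper, mean, sd, lower.tail = FALSE, log.p = TRUE)
    la_lo <- pnorm(upper, mean, sd, log.p = TRUE)
    lb_lo <- pnorm(lower, mean, sd, log.p = TRUE)
    lz_up <- la_up + log1p(-exp(pmin(lb_up - la_up, 0)))
    lz_lo <- la_lo + log1p(-exp(pmin(lb_lo - la_lo, 0)))
    lz <- ifelse(mean <= mid, lz_up, lz_lo)
  }
  out <- ifelse(x < lower | x > upper, -Inf,
                dnorm(x, mean, sd, log = TRUE) - lz)
  if (log) out else exp(out)
}
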