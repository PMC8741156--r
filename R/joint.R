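#' Bivariate drift-EEG population density
#'
#' Log density of one participant's drift-rate and EEG slope measures under
#' the joint model's population distributions: `(v.diff, EEG.diff)` and
#' `(v.mean, EEG.mean)` are each bivariate normal with means `mu + c *
#' delta` (per the group convention) and covariance built from the marginal
#' SDs and the correlation `rho`. With `rho = 0` this factorises into the
#' product of the univariate population terms.
#'
#' @param v_mean,v_diff Subject drift parameters.
#' @param eeg_mean,eeg_diff Observed subject EEG slope measures.
#' @param hypers Tibble `param`, `mu`, `sigma`, `delta` covering `v.diff`
#'   and `v.mean`.
#' @param eeg_hypers Tibble `param`, `mu`, `sigma`, `delta` covering
#'   `EEG.diff` and `EEG.mean`.
#' @param rho Correlation(s): single value shared by both pairs, or named
#'   vector `c(diff = , mean = )`.
#' @param group `"typical"` or `"dyslexia"`.
#' @return Scalar log density (the two pairs' contributions summed);
#'   `-Inf` outside the support, an error for a non-positive-definite
#'   covariance specification (|rho| >= 1 or sigma <= 0).
#' @export
joint_density <- function(v_mean, v_diff, eeg_mean, eeg_diff, hypers,
                          eeg_hypers, rho, group) {
  cc <- if (group == "dyslexia") 1 else -1
  if (length(rho) == 1 && is.null(names(rho))) {
    rho <- c(diff = unname(rho), mean = unname(rho))
  }
  pair <- function(x, e, vp, ep, r) {
    hv <- hypers[hypers$param == vp, ]
    he <- eeg_hypers[eeg_hypers$param == ep, ]
    if (hv$sigma <= 0 || he$sigma <= 0 || abs(r) >= 1) {
      stop("covariance not positive definite (check sigma > 0, |rho| < 1)",
           call. = FALSE)
    }
    m1 <- hv$mu + cc * hv$delta
    m2 <- he$mu + cc * he$delta
    z1 <- (x - m1) / hv$sigma
    z2 <- (e - m2) / he$sigma
    q <- 1 - r^2
    -log(2 * pi) - log(hv$sigma) - log(he$sigma) - 0.5 * log(q) -
      (z1^2 - 2 * r * z1 * z2 + z2^2) / (2 * q)
  }
  pair(v_diff, eeg_diff, "v.diff", "EEG.diff", rho[["diff"]]) +
    pair(v_mean, eeg_mean, "v.mean", "EEG.mean", rho[["mean"]])
}

#' Fit the joint drift-EEG model
#'
#' Convenience wrapper around [fit_hddm()] for the joint model: the
#' population terms for `v.mean` and `v.diff` become bivariate normals with
#' the observed per-participant EEG slope measures, and the correlations
#' `rho_mean`, `rho_diff` (`~ U(-1, 1)`, updated with reflecting boundaries)
#' are estimated — either shared across groups or group-specific.
#' Participants without EEG contribute through the univariate marginals.
#' The sampler defaults follow the joint-model convention: 15 chains, 3000
#' iterations, 1000 burn-in, no migration.
#'
#' @param trials Filtered trial tibble.
#' @param slopes Tibble `participant_id`, `eeg_mean`, `eeg_diff`.
#' @param variant `"shared_rho"` or `"group_rho"`.
#' @param config A [de_config()]; default joint-model settings.
#' @param ages Optional ages for the age-adjusted variant.
#' @param ... Passed to [fit_hddm()].
#' @return An `hddm_fit` with `rho_*` parameters; summarise the evidence
#'   with [bf_table()] (prior density at rho = 0 is exactly 0.5).
#' @export
fit_joint <- function(trials, slopes, variant = c("shared_rho", "group_rho"),
                      config = de_config(n_iter = 3000, burn_in = 1000,
                                         migration_interval = 0),
                      ages = NULL, ...) {
  variant <- match.arg(variant)
  fit_hddm(trials, config = config, ages = ages, slopes = slopes,
           rho_variant = if (variant == "shared_rho") "shared" else
             "by_group", ...)
}

#' Age adjustment of the group-difference inference
#'
#' Two strategies for removing the linear effect of age from every model
#' parameter before interpreting the group differences:
#'
#' * `"covariate"` (default): refit the hierarchical model with each
#'   group-level location shifted by `beta_age * (age - mean(age))`,
#'   `beta_age ~ N(0, 0.5)` per parameter — the age effect and `delta` are
#'   estimated jointly.
#' * `"two_stage"`: take the unadjusted fit's subject-level posterior
#'   means, regress each parameter on age, and fit a small normal
#'   group-difference model (`mu +/- delta`, `sigma`; same priors) to the
#'   residuals by DE-MCMC — the "residuals from the line of best fit"
#'   reading.
#'
#' Both produce a `delta` posterior per parameter. When all ages are equal
#' the covariate model reduces to the unadjusted model.
#'
#' @param trials Filtered trial tibble.
#' @param ages Named numeric vector of ages (one per participant).
#' @param method `"covariate"` or `"two_stage"`.
#' @param priors,config As in [fit_hddm()].
#' @param fit Optional existing unadjusted `hddm_fit` (two-stage only;
#'   avoids refitting).
#' @param ... Passed to [fit_hddm()].
#' @return For `"covariate"`: an `hddm_fit`. For `"two_stage"`: a list of
#'   class `age_adjusted_fit` with `delta_draws` (matrix, one column per
#'   parameter), `residuals`, and the first-stage fit.
#' @export
partial_out_age <- function(trials, ages, method = c("covariate",
                                                     "two_stage"),
                            priors = default_priors(), config = de_config(),
                            fit = NULL, ...) {
  method <- match.arg(method)
  if (method == "covariate") {
    return(fit_hddm(trials, priors = priors, config = config, ages = ages,
                    ...))
  }
  if (is.null(fit)) {
    fit <- fit_hddm(trials, priors = priors, config = config, ...)
  }
  pm <- posterior_matrix(fit)
  ids <- fit$participants
  groups <- ifelse(fit$groups > 0, "dyslexia", "typical")
  age_c <- ages[ids] - mean(ages[ids])
  delta_draws <- list()
  resids <- list()
  for (k in param_names()) {
    means <- vapply(ids, function(id) mean(pm[, paste0(k, "[", id, "]")]),
                    numeric(1))
    res <- unname(residuals(lm(means ~ age_c)))
    resids[[k]] <- res
    gs <- ifelse(groups == "dyslexia", 1, -1)
    dl_row <- as.list(priors[priors$param == k & priors$hyper == "delta", ])
    target <- function(par) {
      mu <- par[1]; sg <- par[2]; dl <- par[3]
      if (sg <= 0) return(-Inf)
      sum(dnorm(res, mu + gs * dl, sg, log = TRUE)) +
        dnorm(mu, 0, 0.5, log = TRUE) +
        dgamma(sg, 1, 1, log = TRUE) +
        prior_logdens(dl_row, dl)
    }
    cfg <- de_config(n_chains = config$n_chains,
                     n_iter = min(config$n_iter, 1500),
                     burn_in = min(config$burn_in, 500),
                     migration_interval = 0, seed = config$seed + 17)
    init <- cbind(rnorm(cfg$n_chains, mean(res), 0.1),
                  abs(rnorm(cfg$n_chains, sd(res), sd(res) / 4)) + 1e-3,
                  rnorm(cfg$n_chains, 0, 0.01))
    ds <- de_sample(target, 3, cfg, init = init)
    delta_draws[[k]] <- posterior_matrix(ds)[, 3]
  }
  structure(list(delta_draws = do.call(cbind, delta_draws),
                 residuals = resids, first_stage = fit,
                 method = "two_stage"),
            class = "age_adjusted_fit")
}
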