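#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy posterior summaries
#'
#' One row per model parameter with posterior mean, SD, central 95%
#' credible interval and (when at least two chains are available) the
#' Gelman-Rubin R-hat.
#'
#' @param x A `de_samples` or `hddm_fit` object.
#' @param pars Optional parameter subset (names or regular expression via
#'   `grep = TRUE`).
#' @param grep Treat `pars` as a regular expression.
#' @param ... Unused.
#' @return A tibble: `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`, `rhat`.
#' @method tidy de_samples
#' @export
tidy.de_samples <- function(x, pars = NULL, grep = FALSE, ...) {
  pm <- posterior_matrix(x)
  keep <- colnames(pm)
  if (!is.null(pars)) {
    keep <- if (grep) grep(pars, keep, value = TRUE) else
      intersect(pars, keep)
  }
  rhat <- tryCatch(gelman_rubin(x), error = function(e) NULL)
  purrr::map_dfr(keep, function(p) {
    v <- pm[, p]
    tibble::tibble(term = p, estimate = mean(v), std.error = sd(v),
                   conf.low = unname(quantile(v, 0.025)),
                   conf.high = unname(quantile(v, 0.975)),
                   rhat = if (is.null(rhat)) NA_real_ else unname(rhat[p]))
  })
}

#' @method tidy hddm_fit
#' @export
tidy.hddm_fit <- function(x, pars = NULL, grep = FALSE, ...) {
  tidy.de_samples(x, pars = pars, grep = grep, ...)
}

#' One-line fit summary
#'
#' @param x An `hddm_fit`.
#' @param ... Unused.
#' @return A one-row tibble: participant count, chains, iterations,
#'   burn-in, block acceptance rates, the largest group-level R-hat, and
#'   flags for the joint / age-adjusted variants.
#' @method glance hddm_fit
#' @export
glance.hddm_fit <- function(x, ...) {
  hyper <- grep("^(mu|sigma|delta)_", x$par_names, value = TRUE)
  rh <- tryCatch(gelman_rubin(x)[hyper], error = function(e) NA_real_)
  tibble::tibble(
    n_participants = length(x$participants),
    n_chains = x$config$n_chains,
    n_iter = x$config$n_iter,
    burn_in = x$config$burn_in,
    accept_subject = unname(x$accept["subject"]),
    accept_hyper = unname(x$accept["hyper"]),
    max_rhat_group_level = max(rh, na.rm = TRUE),
    joint = isTRUE(x$joint),
    age_adjusted = isTRUE(x$age_adjusted))
}

#' @export
print.hddm_fit <- function(x, ...) {
  cat("Hierarchical diffusion model fit",
      if (isTRUE(x$joint)) "(joint drift-EEG model)" else "", "\n")
  cat("  participants:", length(x$participants),
      " chains:", x$config$n_chains,
      " iterations:", x$config$n_iter,
      " (burn-in ", x$config$burn_in, ")\n", sep = "")
  cat("  acceptance: subject ", signif(x$accept["subject"], 3),
      ", hyper ", signif(x$accept["hyper"], 3), "\n", sep = "")
  invisible(x)
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design: 2 groups x", x$n_per_group, "participants,",
      length(x$tasks), "tasks\n")
  cat("  ", x$blocks_per_task, " blocks x ", x$trials_per_block,
      " trials = ", x$trials_per_task, " trials/task (",
      x$catch_per_block, " catch/block), deadline ", x$deadline, " s\n",
      sep = "")
  invisible(x)
}
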