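#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Posterior density plot of the group-difference parameters
#'
#' Prior and posterior densities for every `delta` (and, for joint fits,
#' `rho`) parameter; negative values reflect lower parameter values in the
#' dyslexia group.
#'
#' @param object An `hddm_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hddm_fit
#' @export
autoplot.hddm_fit <- function(object, ...) {
  pm <- posterior_matrix(object)
  pars <- grep("^delta_", object$par_names, value = TRUE)
  if (isTRUE(object$joint)) {
    pars <- c(pars, grep("^rho_", object$par_names, value = TRUE))
  }
  post <- purrr::map_dfr(pars, function(p)
    tibble::tibble(parameter = p, value = pm[, p], which = "posterior"))
  pri <- purrr::map_dfr(pars, function(p) {
    if (grepl("^rho_", p)) {
      x <- seq(-0.999, 0.999, length.out = 200)
      tibble::tibble(parameter = p, x = x, d = dunif(x, -1, 1))
    } else {
      k <- sub("^delta_", "", p)
      row <- object$priors[object$priors$param == k &
                             object$priors$hyper == "delta", ]
      x <- seq(-4 * row$p2, 4 * row$p2, length.out = 200)
      tibble::tibble(parameter = p, x = x, d = dnorm(x, row$p1, row$p2))
    }
  })
  ggplot2::ggplot(post, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "purple", alpha = 0.4) +
    ggplot2::geom_line(data = pri,
                       ggplot2::aes(x = .data$x, y = .data$d),
                       colour = "darkgreen") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "group difference", y = "density")
}

#' Deconvolved regression waveforms
#'
#' The FIR beta waveforms per event type and difficulty level, i.e. the
#' unmixed stimulus-locked and response-locked evoked responses.
#'
#' @param object A `deconv_erp`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot deconv_erp
#' @export
autoplot.deconv_erp <- function(object, ...) {
  ggplot2::ggplot(object$betas,
                  ggplot2::aes(x = .data$lag_s * 1000, y = .data$beta,
                               colour = .data$difficulty)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~event_type) +
    ggplot2::labs(x = "lag (ms)", y = "beta (µV)",
                  subtitle = paste0("ridge λ = ", object$lambda))
}

#' Defective-CDF quantile plot
#'
#' Observed (and optionally model-predicted) defective cumulative quantile
#' summaries per group and difficulty: RT quantiles scaled by response
#' probability, with the miss mass drawn at the deadline.
#'
#' @param observed Output of [defective_quantiles()] on observed trials.
#' @param predicted Optional output of [defective_quantiles()] on
#'   [posterior_predict()] trials.
#' @param deadline Deadline (seconds) at which the miss mass is drawn.
#' @return A ggplot.
#' @export
plot_defective_quantiles <- function(observed, predicted = NULL,
                                     deadline = 2.5) {
  q <- dplyr::mutate(observed$quantiles, source = "observed")
  if (!is.null(predicted)) {
    q <- dplyr::bind_rows(
      q, dplyr::mutate(predicted$quantiles, source = "predicted"))
  }
  m <- dplyr::mutate(observed$misses, source = "observed")
  if (!is.null(predicted)) {
    m <- dplyr::bind_rows(
      m, dplyr::mutate(predicted$misses, source = "predicted"))
  }
  ggplot2::ggplot(q, ggplot2::aes(x = .data$rt, y = .data$cum_prob,
                                  colour = .data$correct,
                                  linetype = .data$source)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_point(data = m,
                        ggplot2::aes(x = deadline, y = .data$p_miss,
                                     shape = .data$source),
                        inherit.aes = FALSE) +
    ggplot2::facet_grid(group ~ difficulty) +
    ggplot2::labs(x = "RT (s)", y = "defective cumulative probability")
}
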