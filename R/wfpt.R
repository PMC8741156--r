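#' Diffusion model parameters
#'
#' Bundle and validate the five parameters of the two-bound Wiener diffusion
#' process used throughout the package: boundary separation `a`, relative
#' starting point `z_rel` (= z/a, the bias toward the upper/right bound),
#' non-decision time `ter` (seconds), drift-rate `v` (evidence units per
#' second), and the within-trial noise SD `s`, fixed at 0.1 by convention to
#' resolve the model's scaling degeneracy.
#'
#' @param a Boundary separation, > 0. Indexes response caution.
#' @param z_rel Relative starting point in (0, 1); 0.5 is unbiased.
#' @param ter Non-decision time in seconds, >= 0.
#' @param v Drift-rate; sign encodes direction (positive = toward the
#'   upper/right bound).
#' @param s Within-trial noise SD (default 0.1).
#' @return A named list of class `diffusion_params`.
#' @export
#' @examples
#' diffusion_params(a = 0.1, z_rel = 0.5, ter = 0.3, v = 0.2)
diffusion_params <- function(a, z_rel = 0.5, ter = 0.3, v = 0.2, s = 0.1) {
  if (!is.numeric(a) || a <= 0) stop("`a` must be > 0", call. = FALSE)
  if (z_rel <= 0 || z_rel >= 1) stop("`z_rel` must lie in (0, 1)", call. = FALSE)
  if (ter < 0) stop("`ter` must be >= 0", call. = FALSE)
  if (s <= 0) stop("`s` must be > 0", call. = FALSE)
  structure(list(a = a, z_rel = z_rel, ter = ter, v = v, s = s),
            class = "diffusion_params")
}

as_diffusion_params <- function(x) {
  if (inherits(x, "diffusion_params")) return(x)
  do.call(diffusion_params, as.list(x))
}

#' Wiener first-passage-time density
#'
#' Defective density of absorption at one bound at total time `t` (decision
#' time plus non-decision time). Computed with the dual small-time/large-time
#' series representation, picking whichever needs fewer terms at the
#' requested accuracy.
#'
#' @param t Total response time(s), seconds.
#' @param bound `"upper"` or `"lower"` — which absorption bound.
#' @param params A [diffusion_params()] object (or coercible list).
#' @return Numeric vector of densities (1/s); zero for `t <= ter`.
#' @export
#' @examples
#' p <- diffusion_params(a = 0.1, v = 0.2)
#' wfpt_density(seq(0.3, 1.5, by = 0.1), "upper", p)
wfpt_density <- function(t, bound = c("upper", "lower"), params) {
  bound <- match.arg(bound)
  p <- as_diffusion_params(params)
  dwfpt_cpp(t, bound == "upper", p$a, p$z_rel, p$ter, p$v, p$s)
}

#' Defective CDF, choice probability and survivor function
#'
#' `wfpt_cdf()` gives the defective CDF of one bound at total time `t` (it
#' asymptotes at that bound's choice probability). `wfpt_choice_prob()` gives
#' the closed-form absorption probability. `wfpt_survivor()` gives
#' S(t) = 1 - CDF_upper(t) - CDF_lower(t), the probability that no bound has
#' been reached by `t` — the likelihood of a non-response at the deadline.
#'
#' @inheritParams wfpt_density
#' @return Numeric vector of probabilities.
#' @export
wfpt_cdf <- function(t, bound = c("upper", "lower"), params) {
  bound <- match.arg(bound)
  p <- as_diffusion_params(params)
  pwfpt_cpp(t, bound == "upper", p$a, p$z_rel, p$ter, p$v, p$s)
}

#' @rdname wfpt_cdf
#' @export
wfpt_choice_prob <- function(bound = c("upper", "lower"), params) {
  bound <- match.arg(bound)
  p <- as_diffusion_params(params)
  choice_prob_cpp(bound == "upper", p$a, p$z_rel, p$v, p$s)
}

#' @rdname wfpt_cdf
#' @export
wfpt_survivor <- function(t, params) {
  p <- as_diffusion_params(params)
  swfpt_cpp(t, p$a, p$z_rel, p$ter, p$v, p$s)
}

#' Simulate first-passage trials
#'
#' Draws single-trial outcomes from the diffusion process by Euler-Maruyama
#' integration with a Brownian-bridge correction for boundary crossings
#' between grid points (removing the first-order discretisation bias).
#' Trials whose total RT exceeds `deadline` are recorded as timeouts.
#'
#' @inheritParams wfpt_density
#' @param n Number of trials.
#' @param deadline Response deadline in seconds (total RT); must exceed `ter`.
#' @param dt Integration step, seconds (default 1e-4).
#' @return A tibble with columns `response` (`"upper"`, `"lower"` or `NA`
#'   for timeout), `rt` (total seconds, `NA` for timeout) and `timeout`.
#' @export
#' @examples
#' set.seed(1)
#' wfpt_simulate(5, diffusion_params(a = 0.1, v = 0.3))
wfpt_simulate <- function(n, params, deadline = 2.5, dt = 1e-4) {
  p <- as_diffusion_params(params)
  if (deadline <= p$ter) stop("`deadline` must exceed `ter`", call. = FALSE)
  m <- sim_wfpt_cpp(n, p$a, p$z_rel, p$ter, p$v, p$s, deadline, dt)
  tibble::tibble(
    response = dplyr::case_when(is.na(m[, 1]) ~ NA_character_,
                                m[, 1] > 0.5 ~ "upper",
                                TRUE ~ "lower"),
    rt = m[, 2],
    timeout = is.na(m[, 1])
  )
}

#' Trial log-likelihood under the diffusion model
#'
#' Log-likelihood contribution of each trial: responded trials contribute the
#' log defective density at the observed RT on the response's bound, with
#' drift signed by the stimulus direction (bounds are the left/right
#' responses; drift is `+v` for rightward stimuli and `-v` for leftward, and
#' `z_rel` is the bias toward the right bound). Timeout trials are treated as
#' non-terminating accumulation trajectories and contribute the log survivor
#' function at the deadline. A responded trial at `rt <= ter` lies outside
#' the model's support and contributes the configurable `penalty` (a large
#' negative number rather than `-Inf`, to keep MCMC arithmetic finite).
#'
#' @param trials A data frame with columns `difficulty` (1 = easy, 2 = hard),
#'   `dir_sign` (+1 rightward, -1 leftward), `response` (1 = right/upper,
#'   0 = left/lower, `NA` = timeout) and `rt` (total seconds, `NA` timeout).
#' @param subject Named numeric vector or list with `a`, `z_rel`, `ter`,
#'   `v_mean`, `v_diff`; per-difficulty drifts are `v_mean + v_diff/2` (easy)
#'   and `v_mean - v_diff/2` (hard).
#' @param s Within-trial noise SD (default 0.1).
#' @param deadline Deadline in seconds (default 2.5).
#' @param penalty Log-likelihood assigned to out-of-support responded trials
#'   (default -1e10).
#' @return The summed log-likelihood (scalar).
#' @export
wfpt_loglik <- function(trials, subject, s = 0.1, deadline = 2.5,
                        penalty = -1e10) {
  stopifnot(all(c("difficulty", "dir_sign", "response", "rt") %in%
                  names(trials)))
  resp <- trials$response
  if (any(!is.na(resp) & !is.na(trials$rt) & trials$rt <= 0)) {
    stop("responded trials must have rt > 0", call. = FALSE)
  }
  par <- matrix(as.numeric(c(subject[["a"]], subject[["z_rel"]],
                             subject[["ter"]], subject[["v_mean"]],
                             subject[["v_diff"]])), nrow = 1)
  wfpt_loglik_cpp(par, as.integer(trials$difficulty),
                  as.numeric(trials$dir_sign), as.numeric(resp),
                  as.numeric(trials$rt), s, deadline, penalty)[1]
}
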