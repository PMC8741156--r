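#' Behavioural study design
#'
#' Describes the two-task, two-group global-motion experiment the generator
#' emulates: per task, `blocks_per_task` experimental blocks each containing
#' `reps_per_cell` repetitions of every difficulty x direction cell plus
#' `catch_per_block` very-easy catch trials, a 2.5 s response deadline, and
#' jittered fixation / random-motion / offset periods that determine event
#' spacing for the EEG deconvolution.
#'
#' With the defaults, each block holds 9 x 2 x 2 + 2 = 38 trials and each
#' task 4 x 38 = 152 trials.
#'
#' @param n_per_group Participants per group.
#' @param tasks Task labels.
#' @param blocks_per_task Experimental blocks per task.
#' @param reps_per_cell Repetitions per difficulty x direction cell per block.
#' @param catch_per_block Catch trials per block (maximal-coherence probes).
#' @param deadline Response deadline, seconds (total RT).
#' @param rt_floor Lower RT bound used by the exclusion filter, seconds.
#' @param jitter_fixation,jitter_random_motion,jitter_offset Min/max seconds
#'   of the uniformly jittered periods (fixation, pre-stimulus random motion,
#'   post-trial offset).
#' @return A list of class `study_design` with derived counts
#'   `trials_per_block` and `trials_per_task`.
#' @export
#' @examples
#' d <- study_design()
#' d$trials_per_task # 152
study_design <- function(n_per_group = 25,
                         tasks = c("motion_coherence", "direction_integration"),
                         blocks_per_task = 4,
                         reps_per_cell = 9,
                         catch_per_block = 2,
                         deadline = 2.5,
                         rt_floor = 0.2,
                         jitter_fixation = c(1.0, 1.5),
                         jitter_random_motion = c(1.0, 1.5),
                         jitter_offset = c(0.25, 0.5)) {
  counts <- c(n_per_group = n_per_group, blocks_per_task = blocks_per_task,
              reps_per_cell = reps_per_cell)
  if (any(counts <= 0) || any(counts != round(counts))) {
    stop("counts must be positive integers", call. = FALSE)
  }
  if (catch_per_block < 0) stop("`catch_per_block` must be >= 0", call. = FALSE)
  if (deadline <= 0) stop("`deadline` must be > 0", call. = FALSE)
  trials_per_block <- reps_per_cell * 2L * 2L + catch_per_block
  structure(list(
    n_per_group = as.integer(n_per_group),
    tasks = tasks,
    blocks_per_task = as.integer(blocks_per_task),
    reps_per_cell = as.integer(reps_per_cell),
    catch_per_block = as.integer(catch_per_block),
    deadline = deadline,
    rt_floor = rt_floor,
    jitter_fixation = jitter_fixation,
    jitter_random_motion = jitter_random_motion,
    jitter_offset = jitter_offset,
    trials_per_block = as.integer(trials_per_block),
    trials_per_task = as.integer(blocks_per_task * trials_per_block)
  ), class = "study_design")
}

#' Generator configuration: the planted truth
#'
#' Houses the population-level hyperparameters the behavioural generator
#' draws subjects from, the linear drift-to-EEG link, and the EEG noise
#' model. The five diffusion parameters follow the mu +/- delta group
#' convention (dyslexia = mu + delta, typical = mu - delta); parameter order
#' is `a`, `z`, `ter`, `v.diff`, `v.mean` with `v.diff = v_easy - v_hard`.
#'
#' Default population values place simulated children in the regime the
#' task is designed for: accuracy near ceiling on the easy level and around
#' 0.8 on the difficult level, median RTs around 0.6 s, and roughly 1% of
#' trials running past the 2.5 s deadline. Spreads are moderate so children
#' differ visibly in speed and accuracy without drift-sign flips. The EEG
#' link makes
#' each participant's pre-response ramp slope `alpha0 + alpha1 * v.mean` plus
#' noise, with `link_resid_sd` chosen so the population drift-slope
#' correlation equals `rho_target` (0.44 by default).
#'
#' @param mu,sigma,delta Named length-5 vectors (names `a`, `z`, `ter`,
#'   `v.diff`, `v.mean`) of group-level means, SDs and half-differences.
#' @param catch_drift_multiplier Drift multiplier for catch trials relative
#'   to the easy condition.
#' @param fast_guess_rate Fraction of contaminant fast guesses (uniform RT on
#'   \[0, 0.3\] s, random response) injected per participant.
#' @param alpha0,alpha1 Intercept (microvolt/s) and gain (microvolt/s per
#'   drift unit) of the drift-to-slope link.
#' @param rho_target Population correlation between `v.mean` and the planted
#'   slope implied by the default residual SD. Ignored if `link_resid_sd`
#'   is given.
#' @param link_resid_sd Residual SD of planted slopes (microvolt/s);
#'   `NULL` derives it from `rho_target`.
#' @param ar_coef,noise_sd AR(1) coefficient and innovation-scaled SD of the
#'   continuous EEG noise (microvolts).
#' @param n_channels Channels in the synthetic recording (1 = component
#'   space).
#' @param topography Planted channel topography (length `n_channels`);
#'   default a smooth unimodal profile.
#' @param fs Sampling rate, Hz.
#' @param stim_kernel_amp Amplitudes (microvolts) of the stimulus-locked
#'   kernel, named by difficulty level (`easy`, `hard`).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(mu = c(a = 0.15, z = 0.5, ter = 0.3,
                                    v.diff = 0.15, v.mean = 0.2),
                             sigma = c(a = 0.03, z = 0.05, ter = 0.05,
                                       v.diff = 0.05, v.mean = 0.05),
                             delta = c(a = 0, z = 0, ter = 0,
                                       v.diff = 0, v.mean = 0),
                             catch_drift_multiplier = 2,
                             fast_guess_rate = 0,
                             alpha0 = 0.5, alpha1 = 8,
                             rho_target = 0.44,
                             link_resid_sd = NULL,
                             ar_coef = 0.95, noise_sd = 10,
                             n_channels = 1L, topography = NULL,
                             fs = 250,
                             stim_kernel_amp = c(easy = 8, hard = 6)) {
  pn <- c("a", "z", "ter", "v.diff", "v.mean")
  mu <- mu[pn]; sigma <- sigma[pn]; delta <- delta[pn]
  if (anyNA(mu) || anyNA(sigma) || anyNA(delta)) {
    stop("mu, sigma, delta must be named over a, z, ter, v.diff, v.mean",
         call. = FALSE)
  }
  if (any(sigma <= 0)) stop("all sigma must be > 0", call. = FALSE)
  if (fs <= 0) stop("sampling rate must be > 0", call. = FALSE)
  if (abs(ar_coef) >= 1) stop("AR(1) coefficient must lie in (-1, 1)",
                              call. = FALSE)
  if (fast_guess_rate < 0 || fast_guess_rate > 1) {
    stop("`fast_guess_rate` must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(link_resid_sd)) {
    # slope = alpha0 + alpha1 * v.mean + e; pick sd(e) so that
    # cor(v.mean, slope) = rho_target in the population
    sv <- abs(alpha1) * sigma[["v.mean"]]
    link_resid_sd <- if (sv > 0 && abs(rho_target) > 0 && abs(rho_target) < 1) {
      sv * sqrt(1 / rho_target^2 - 1)
    } else if (sv > 0 && abs(rho_target) >= 1) 0 else 2
  }
  if (is.null(topography)) {
    topography <- if (n_channels == 1L) 1 else {
      x <- seq(-2, 2, length.out = n_channels)
      w <- exp(-x^2)
      w / sqrt(sum(w^2))
    }
  }
  structure(list(mu = mu, sigma = sigma, delta = delta,
                 catch_drift_multiplier = catch_drift_multiplier,
                 fast_guess_rate = fast_guess_rate,
                 alpha0 = alpha0, alpha1 = alpha1,
                 rho_target = rho_target, link_resid_sd = link_resid_sd,
                 ar_coef = ar_coef, noise_sd = noise_sd,
                 n_channels = as.integer(n_channels),
                 topography = topography, fs = fs,
                 stim_kernel_amp = stim_kernel_amp,
                 s = 0.1),
            class = "generator_config")
}

#' Block points score
#'
#' End-of-block feedback score: `(1 / median RT) * number correct * 2`,
#' rounded to the nearest integer, with scores under 10 replaced by 10 to
#' maintain motivation.
#'
#' @param median_rt Median response time of the block, seconds (> 0).
#' @param n_correct Number of correct responses in the block.
#' @return Integer points.
#' @export
#' @examples
#' block_points(1.0, 30) # 60
#' block_points(2.0, 4)  # raw 4 -> floored to 10
block_points <- function(median_rt, n_correct) {
  if (any(median_rt <= 0)) stop("`median_rt` must be > 0", call. = FALSE)
  raw <- round(n_correct * 2 / median_rt)
  as.integer(pmax(raw, 10L))
}
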