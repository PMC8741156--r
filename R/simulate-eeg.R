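#' Planted EEG kernels
#'
#' The synthetic continuous EEG is a sum of event-locked kernels plus AR(1)
#' noise. `stim_kernel_wave()` is the stimulus-locked kernel: a half-sine
#' burst over the 600 ms after stimulus onset whose amplitude depends on
#' difficulty (the evoked response is larger for easy, high-coherence
#' motion). `resp_kernel_wave()` is the response-locked kernel: a linear
#' ramp over the 400 ms before the response with the participant's planted
#' slope (microvolt/s), decaying back to zero over the 200 ms after the
#' response — a schematic centro-parietal build-up.
#'
#' @param config A [generator_config()].
#' @param difficulty `"easy"`, `"hard"` or `"catch"` (catch uses the easy
#'   amplitude).
#' @param slope Ramp slope in microvolt/s.
#' @param fs Sampling rate, Hz.
#' @return A tibble with `lag_s` (seconds relative to the event) and
#'   `amplitude` (microvolts).
#' @export
stim_kernel_wave <- function(config, difficulty = "easy") {
  amp <- if (difficulty == "hard") config$stim_kernel_amp[["hard"]] else
    config$stim_kernel_amp[["easy"]]
  lag <- seq(0, 0.6 - 1 / config$fs, by = 1 / config$fs)
  tibble::tibble(lag_s = lag, amplitude = amp * sin(pi * lag / 0.6))
}

#' @rdname stim_kernel_wave
#' @export
resp_kernel_wave <- function(slope, fs = 250) {
  lag <- seq(-0.4, 0.2, by = 1 / fs)
  peak <- slope * 0.4
  amp <- ifelse(lag <= 0, slope * (lag + 0.4), peak * (1 - lag / 0.2))
  tibble::tibble(lag_s = lag, amplitude = amp)
}

#' Simulate continuous EEG for each participant
#'
#' Builds a continuous recording per participant and task by summing
#' stimulus-locked kernels at every stimulus onset and response-locked
#' kernels at every response (timeout trials contribute no response event),
#' then adding AR(1) noise. Stimulus- and response-locked activity overlap
#' in time exactly as in the task, with the degree of overlap tied to each
#' trial's RT — the structure the deconvolution stage exists to unmix. With
#' more than one channel the component is projected through the planted
#' topography and independent channel noise is added.
#'
#' @param sim Output of [simulate_behaviour()] (list with `trials`,
#'   `subjects`), or a trial tibble plus `subjects` given separately.
#' @param config A [generator_config()].
#' @param seed Integer seed (slopes and noise substreams derive from it).
#' @param task Which task's recordings to build (default: first task
#'   present).
#' @param subjects Optional subjects tibble with planted slopes (from
#'   [simulate_slopes()]); drawn automatically otherwise.
#' @return A named list (by participant id) of `eeg_recording` objects:
#'   `data` (channels x samples matrix, microvolts), `fs`, `events` (tibble
#'   `time_s`, `type`, `difficulty`), `slopes` (planted slopes), `task`.
#' @export
simulate_eeg <- function(sim, config = generator_config(), seed = 1L,
                         task = NULL, subjects = NULL) {
  trials <- if (is.data.frame(sim)) sim else sim$trials
  if (is.null(subjects)) {
    subjects <- if (is.data.frame(sim)) stop("supply `subjects`") else
      sim$subjects
  }
  if (!"slope_easy" %in% names(subjects)) {
    subjects <- simulate_slopes(subjects, config, seed)
  }
  if (is.null(task)) task <- trials$task[1]
  trials <- trials[trials$task == task, ]
  ids <- unique(trials$participant_id)
  set.seed(seed + 224737L)
  noise_seeds <- sample.int(.Machine$integer.max - 1L, length(ids))

  recs <- purrr::map(seq_along(ids), function(i) {
    id <- ids[i]
    tr <- trials[trials$participant_id == id, ]
    su <- subjects[subjects$participant_id == id & subjects$task == task, ]
    set.seed(noise_seeds[i])
    build_recording(tr, su, config)
  })
  names(recs) <- ids
  recs
}

build_recording <- function(tr, su, config) {
  fs <- config$fs
  if (any(!is.na(tr$resp_time_s) & tr$resp_time_s < tr$stim_time_s)) {
    stop("response precedes stimulus", call. = FALSE)
  }
  t_end <- max(tr$stim_time_s, tr$resp_time_s, na.rm = TRUE) + 2
  ns <- ceiling(t_end * fs)
  comp <- numeric(ns)

  add_kernel <- function(comp, onset_s, wave) {
    i0 <- round(onset_s * fs) + 1L
    idx <- i0 + seq_along(wave) - 1L
    keep <- idx >= 1L & idx <= ns
    comp[idx[keep]] <- comp[idx[keep]] + wave[keep]
    comp
  }

  for (k in seq_len(nrow(tr))) {
    sk <- stim_kernel_wave(config, tr$difficulty[k])
    comp <- add_kernel(comp, tr$stim_time_s[k], sk$amplitude)
    if (!tr$timeout[k]) {
      sl <- if (tr$difficulty[k] == "hard") su$slope_hard else su$slope_easy
      rk <- resp_kernel_wave(sl, fs)
      comp <- add_kernel(comp, tr$resp_time_s[k] - 0.4, rk$amplitude)
    }
  }

  if (config$noise_sd > 0) {
    comp <- comp + ar1_noise(ns, config$ar_coef, config$noise_sd)
  }

  if (config$n_channels > 1L) {
    data <- outer(config$topography, comp)
    if (config$noise_sd > 0) {
      data <- data + matrix(rnorm(length(data), 0, config$noise_sd),
                            nrow = config$n_channels)
    }
  } else {
    data <- matrix(comp, nrow = 1)
  }

  events <- dplyr::bind_rows(
    tibble::tibble(time_s = tr$stim_time_s, type = "stimulus",
                   difficulty = tr$difficulty),
    tibble::tibble(time_s = tr$resp_time_s[!tr$timeout], type = "response",
                   difficulty = tr$difficulty[!tr$timeout])
  )
  events <- events[order(events$time_s), ]
  if (any(diff(events$time_s) < 1 / fs - 1e-9)) {
    stop("events closer together than one sample", call. = FALSE)
  }

  structure(list(data = data, fs = fs, events = events,
                 slopes = c(easy = su$slope_easy, hard = su$slope_hard),
                 participant_id = tr$participant_id[1],
                 task = tr$task[1]),
            class = "eeg_recording")
}

# stationary AR(1) noise with marginal SD `sd`
ar1_noise <- function(n, phi, sd) {
  innov_sd <- sd * sqrt(1 - phi^2)
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sd)
  e <- rnorm(n - 1, 0, innov_sd)
  if (abs(phi) > 0) {
    x <- stats::filter(c(x[1], e), phi, method = "recursive")
    as.numeric(x)
  } else {
    c(x[1], e)
  }
}
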