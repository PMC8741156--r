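#' Simulate the behavioural experiment
#'
#' Draws true diffusion parameters for every participant from the
#' group-level distributions (dyslexia = mu + delta, typical = mu - delta;
#' truncated normals for `a`, `z`, `ter`, normals for `v.diff`, `v.mean`)
#' and generates every trial of the two-task design from the Wiener
#' first-passage process. Trials whose first passage exceeds the 2.5 s
#' deadline are recorded as timeouts. Catch trials run at
#' `catch_drift_multiplier` times the easy drift and are flagged. A
#' configurable fraction of fast-guess contaminants (uniform RT on \[0, 0.3\]
#' s, random response) can be injected to exercise the RT filter.
#'
#' All randomness flows from `seed` through per-participant substreams, so
#' the same seed reproduces the identical trial table and regenerating a
#' single participant is stable under changes of `n_per_group`.
#'
#' @param design A [study_design()].
#' @param config A [generator_config()].
#' @param seed Integer root seed.
#' @return A list with `trials` (one row per trial: `participant_id`,
#'   `group`, `task`, `block`, `trial`, `difficulty`, `direction`,
#'   `response`, `rt_s`, `timeout`, `catch`, `correct`, `stim_time_s`,
#'   `resp_time_s`) and `subjects` (true per-participant parameters).
#' @export
#' @examples
#' sim <- simulate_behaviour(study_design(n_per_group = 2), seed = 1)
#' dplyr::count(sim$trials, participant_id, task)
simulate_behaviour <- function(design = study_design(),
                               config = generator_config(),
                               seed = 1L) {
  stopifnot(inherits(design, "study_design"),
            inherits(config, "generator_config"))
  set.seed(seed)
  n <- 2L * design$n_per_group
  subseeds <- sample.int(.Machine$integer.max - 1L, n)
  groups <- rep(c("typical", "dyslexia"), each = design$n_per_group)
  ids <- sprintf("p%03d", seq_len(n))

  subjects <- purrr::map2_dfr(seq_len(n), groups, function(i, grp) {
    set.seed(subseeds[i])
    cc <- if (grp == "dyslexia") 1 else -1
    purrr::map_dfr(design$tasks, function(task) {
      tibble::tibble(
        participant_id = ids[i], group = grp, task = task,
        a = rtnorm1(config$mu[["a"]] + cc * config$delta[["a"]],
                    config$sigma[["a"]], 0, Inf),
        z = rtnorm1(config$mu[["z"]] + cc * config$delta[["z"]],
                    config$sigma[["z"]], 0, 1),
        ter = rtnorm1(config$mu[["ter"]] + cc * config$delta[["ter"]],
                      config$sigma[["ter"]], 0, Inf),
        v.diff = rnorm(1, config$mu[["v.diff"]] + cc * config$delta[["v.diff"]],
                       config$sigma[["v.diff"]]),
        v.mean = rnorm(1, config$mu[["v.mean"]] + cc * config$delta[["v.mean"]],
                       config$sigma[["v.mean"]])
      )
    })
  })

  trials <- purrr::map_dfr(seq_len(n), function(i) {
    set.seed(subseeds[i] %% 1000000L + 7L * i) # trial substream
    purrr::map_dfr(design$tasks, function(task) {
      su <- subjects[subjects$participant_id == ids[i] &
                       subjects$task == task, ]
      simulate_participant_task(su, design, config, groups[i], task)
    })
  })

  list(trials = trials, subjects = subjects)
}

# one participant x task block structure + Wiener simulation + trial clock
simulate_participant_task <- function(su, design, config, group, task) {
  cells <- tidyr::expand_grid(difficulty = c("easy", "hard"),
                              direction = c("left", "right"))
  blocks <- purrr::map_dfr(seq_len(design$blocks_per_task), function(b) {
    main <- cells[rep(seq_len(nrow(cells)), design$reps_per_cell), ]
    main$catch <- FALSE
    if (design$catch_per_block > 0) {
      catch <- tibble::tibble(
        difficulty = "catch",
        direction = sample(c("left", "right"), design$catch_per_block,
                           replace = TRUE),
        catch = TRUE)
      main <- dplyr::bind_rows(main, catch)
    }
    main <- main[sample.int(nrow(main)), ]
    main$block <- b
    main
  })
  nt <- nrow(blocks)
  v_easy <- su$v.mean + su$v.diff / 2
  v_hard <- su$v.mean - su$v.diff / 2
  v_mag <- dplyr::case_when(blocks$difficulty == "easy" ~ v_easy,
                            blocks$difficulty == "hard" ~ v_hard,
                            TRUE ~ config$catch_drift_multiplier * v_easy)
  v_signed <- ifelse(blocks$direction == "right", v_mag, -v_mag)
  m <- sim_wfpt_cpp(nt, su$a, su$z, su$ter, v_signed, config$s,
                    design$deadline, 1e-4)
  response <- dplyr::case_when(is.na(m[, 1]) ~ NA_character_,
                               m[, 1] > 0.5 ~ "right", TRUE ~ "left")
  rt <- m[, 2]
  if (config$fast_guess_rate > 0) {
    fg <- runif(nt) < config$fast_guess_rate
    rt[fg] <- runif(sum(fg), 0, 0.3)
    response[fg] <- sample(c("left", "right"), sum(fg), replace = TRUE)
  }
  timeout <- is.na(response)

  # trial clock: fixation -> random motion -> stimulus -> (response|deadline)
  # -> offset; stimulus and response times live on one continuous recording
  fix <- runif(nt, design$jitter_fixation[1], design$jitter_fixation[2])
  rm_ <- runif(nt, design$jitter_random_motion[1],
               design$jitter_random_motion[2])
  off <- runif(nt, design$jitter_offset[1], design$jitter_offset[2])
  dur <- fix + rm_ + ifelse(timeout, design$deadline, rt) + off
  t0 <- cumsum(c(0, head(dur, -1)))
  stim_time <- t0 + fix + rm_

  tibble::tibble(
    participant_id = su$participant_id[1], group = group, task = task,
    block = blocks$block,
    trial = seq_len(nt),
    difficulty = blocks$difficulty,
    direction = blocks$direction,
    response = response,
    rt_s = rt,
    timeout = timeout,
    catch = blocks$catch,
    correct = !timeout & response == blocks$direction,
    stim_time_s = stim_time,
    resp_time_s = ifelse(timeout, NA_real_, stim_time + rt)
  )
}

# single truncated-normal draw by inverse-CDF (exact, vectorisable)
rtnorm1 <- function(mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(length(mean), plo, phi), mean, sd)
}

#' Planted EEG slopes from the drift-to-slope link
#'
#' Draws each participant's true pre-response ramp slope per difficulty
#' level from the generator's linear link: `slope_d = alpha0 + alpha1 * v_d
#' + e`, with `e ~ N(0, link_resid_sd)` shared scale. Averaging over
#' difficulties gives a planted `EEG.mean` whose population correlation with
#' `v.mean` equals the configured target.
#'
#' @param subjects The `subjects` tibble from [simulate_behaviour()].
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return `subjects` with added `slope_easy`, `slope_hard`, `eeg_mean`,
#'   `eeg_diff` columns (microvolt/s).
#' @export
simulate_slopes <- function(subjects, config = generator_config(),
                            seed = 1L) {
  set.seed(seed + 104729L)
  n <- nrow(subjects)
  v_easy <- subjects$v.mean + subjects$v.diff / 2
  v_hard <- subjects$v.mean - subjects$v.diff / 2
  rs <- if (is.finite(config$link_resid_sd)) config$link_resid_sd else 0
  # residual decomposed into a mean component (SD exactly link_resid_sd, so
  # cor(v.mean, eeg_mean) hits the configured target) and an independent
  # difference component
  e_mean <- rnorm(n, 0, rs)
  e_diff <- rnorm(n, 0, rs)
  slope_easy <- config$alpha0 + config$alpha1 * v_easy + e_mean + e_diff / 2
  slope_hard <- config$alpha0 + config$alpha1 * v_hard + e_mean - e_diff / 2
  dplyr::mutate(subjects,
                slope_easy = slope_easy, slope_hard = slope_hard,
                eeg_mean = (slope_easy + slope_hard) / 2,
                eeg_diff = slope_easy - slope_hard)
}
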