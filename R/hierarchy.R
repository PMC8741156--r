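#' Pre-modelling trial filter
#'
#' Applies the behavioural exclusion rules ahead of fitting: responded
#' trials faster than `rt_floor` (200 ms by default) are removed as
#' anticipations, catch trials are removed, and timeout trials are retained
#' as censored records (they enter the likelihood through the survivor
#' function, not the density). Percentages removed are reported per group.
#'
#' @param trials Trial tibble from [simulate_behaviour()] (columns
#'   `group`, `difficulty`, `response`, `rt_s`, `timeout`, `catch`).
#' @param rt_floor Exclusion threshold in seconds (default 0.2).
#' @return A list: `trials` (the modelling table) and `report` (per-group
#'   counts and percentages of fast-RT and catch exclusions and retained
#'   timeouts).
#' @export
filter_trials <- function(trials, rt_floor = 0.2) {
  fast <- !trials$timeout & !is.na(trials$rt_s) & trials$rt_s < rt_floor
  is_catch <- trials$catch
  report <- trials |>
    dplyr::mutate(fast = fast) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_fast_removed = sum(.data$fast & !.data$catch),
      pct_fast_removed = 100 * mean(.data$fast & !.data$catch),
      n_catch_removed = sum(.data$catch),
      n_timeout_retained = sum(.data$timeout & !.data$catch),
      pct_timeout = 100 * mean(.data$timeout & !.data$catch),
      .groups = "drop")
  list(trials = trials[!fast & !is_catch, , drop = FALSE], report = report)
}

# internal: modelling covariates for the likelihood
# difficulty 1 = easy, 2 = hard; dir_sign +1 rightward; response 1 = right
prepare_trials <- function(trials) {
  stopifnot(all(trials$difficulty %in% c("easy", "hard")))
  tibble::tibble(
    participant_id = trials$participant_id,
    group = trials$group,
    difficulty = ifelse(trials$difficulty == "easy", 1L, 2L),
    dir_sign = ifelse(trials$direction == "right", 1, -1),
    response = ifelse(trials$timeout, NA_real_,
                      ifelse(trials$response == "right", 1, 0)),
    rt = ifelse(trials$timeout, NA_real_, trials$rt_s))
}

# split prepared trials into a per-participant list of covariate vectors
split_trials <- function(prep) {
  ids <- unique(prep$participant_id)
  out <- lapply(ids, function(id) {
    tr <- prep[prep$participant_id == id, ]
    list(difficulty = as.integer(tr$difficulty),
         dir_sign = as.numeric(tr$dir_sign),
         response = as.numeric(tr$response),
         rt = as.numeric(tr$rt),
         group = tr$group[1])
  })
  names(out) <- ids
  out
}

#' Subject-level log density under the group model
#'
#' Log density of one participant's parameter vector under the group-level
#' distributions: truncated normals on (0, Inf) for `a` and `ter`, a
#' truncated normal on (0, 1) for `z`, and normals for `v.diff` and
#' `v.mean`, each centred at `mu + c * delta` with `c = +1` for the
#' dyslexia group and `-1` for the typical group. Truncation constants are
#' included so each factor is a normalised density. Values outside a
#' parameter's support give `-Inf`.
#'
#' @param theta Named numeric vector (or 1-row data frame) with `a`, `z`,
#'   `ter`, `v.diff`, `v.mean`.
#' @param hypers Tibble with columns `param`, `mu`, `sigma`, `delta`.
#' @param group `"typical"` or `"dyslexia"`.
#' @param age_offset Optional named vector of per-parameter location shifts
#'   (the age-regression term `beta_age * (age - mean(age))`).
#' @return Scalar log density.
#' @export
subject_logdens <- function(theta, hypers, group,
                            age_offset = NULL) {
  cc <- if (group == "dyslexia") 1 else -1
  h <- hypers[match(param_names(), hypers$param), ]
  loc <- h$mu + cc * h$delta
  if (!is.null(age_offset)) loc <- loc + age_offset[param_names()]
  x <- as.numeric(theta[param_names()])
  comp <- subject_logdens_components(
    matrix(x, nrow = 1, dimnames = list(NULL, param_names())),
    matrix(loc, nrow = 1), matrix(h$sigma, nrow = 1))
  sum(comp)
}

param_names <- function() c("a", "z", "ter", "v.diff", "v.mean")

# vectorised per-parameter subject-level log densities.
# x, loc, sigma: matrices n x 5 (columns in param_names() order).
# Returns an n x 5 matrix of log densities.
subject_logdens_components <- function(x, loc, sigma) {
  out <- matrix(NA_real_, nrow(x), 5)
  bounds <- list(c(0, Inf), c(0, 1), c(0, Inf), c(-Inf, Inf), c(-Inf, Inf))
  for (k in 1:5) {
    b <- bounds[[k]]
    if (is.finite(b[1]) || is.finite(b[2])) {
      out[, k] <- dtnorm(x[, k], loc[, k], sigma[, k], b[1], b[2], log = TRUE)
    } else {
      out[, k] <- dnorm(x[, k], loc[, k], sigma[, k], log = TRUE)
    }
  }
  colnames(out) <- param_names()
  out
}

# log hyperprior for a hypers tibble (param, mu, sigma, delta) under priors
hyperprior_logdens <- function(hypers, priors) {
  tot <- 0
  for (i in seq_len(nrow(hypers))) {
    p <- hypers$param[i]
    for (h in c("mu", "sigma", "delta")) {
      row <- priors[priors$param == p & priors$hyper == h, ]
      tot <- tot + prior_logdens(as.list(row), hypers[[h]][i])
    }
  }
  tot
}

#' Joint log posterior of the hierarchical diffusion model
#'
#' Sum of all trial log-likelihoods (Wiener densities for responses,
#' survivor mass for timeouts), all subject-level log densities under the
#' group model, and the log hyperprior. Expects a pre-filtered trial table
#' (see [filter_trials()]).
#'
#' @param theta Tibble of subject parameters: `participant_id`, `group`,
#'   `a`, `z`, `ter`, `v.diff`, `v.mean`.
#' @param hypers Tibble `param`, `mu`, `sigma`, `delta` over the 5
#'   parameters.
#' @param trials Filtered trial tibble.
#' @param priors A [default_priors()] spec.
#' @param s Within-trial noise SD (default 0.1).
#' @param deadline Deadline, seconds.
#' @param penalty Out-of-support log-likelihood penalty.
#' @param ages Optional named vector of ages (one per participant); if
#'   given, `beta_age` (named per-parameter vector) shifts group locations
#'   by `beta_age * (age - mean(age))`.
#' @param beta_age Optional per-parameter age slopes (default zeros).
#' @return Scalar log posterior (finite on the prior's support).
#' @export
log_posterior <- function(theta, hypers, trials, priors = default_priors(),
                          s = 0.1, deadline = 2.5, penalty = -1e10,
                          ages = NULL, beta_age = NULL) {
  prep <- prepare_trials(trials)
  dat <- split_trials(prep)
  ll <- 0
  age_c <- if (!is.null(ages)) ages - mean(ages) else NULL
  if (is.null(beta_age)) beta_age <- setNames(numeric(5), param_names())
  for (id in theta$participant_id) {
    row <- theta[theta$participant_id == id, ]
    if (id %in% names(dat)) {
      d <- dat[[id]]
      par <- matrix(c(row$a, row$z, row$ter, row$v.mean, row$v.diff),
                    nrow = 1)
      ll <- ll + wfpt_loglik_cpp(par, d$difficulty, d$dir_sign, d$response,
                                 d$rt, s, deadline, penalty)[1]
    }
    off <- if (!is.null(age_c)) beta_age * age_c[[id]] else NULL
    ll <- ll + subject_logdens(
      c(a = row$a, z = row$z, ter = row$ter,
        v.diff = row$v.diff, v.mean = row$v.mean),
      hypers, row$group, age_offset = off)
  }
  ll <- ll + hyperprior_logdens(hypers, priors)
  if (!is.null(age_c)) {
    ll <- ll + sum(dnorm(beta_age, 0, 0.5, log = TRUE))
  }
  ll
}
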