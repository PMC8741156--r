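#' Fit the hierarchical diffusion model by DE-MCMC
#'
#' Samples the joint posterior of all subject-level diffusion parameters and
#' the group-level hyperparameters (`mu`, `sigma`, `delta` per parameter)
#' with a blocked differential-evolution MCMC: each sweep updates every
#' participant's 5-parameter block conditional on the hyperparameters, then
#' each hyperparameter triple conditional on the subject parameters, with
#' periodic chain migration on the configured schedule. Timeout trials enter
#' through the survivor function at the deadline; the trial table must
#' already be filtered (see [filter_trials()]).
#'
#' With `ages`, group-level locations gain an in-model age covariate:
#' `mu + c * delta + beta_age * (age - mean(age))`, `beta_age ~ N(0, 0.5)`
#' per parameter, so the `delta` posterior is adjusted for age.
#'
#' With `slopes`, the model becomes the joint drift-EEG model: the
#' univariate population terms for `v.mean` and `v.diff` are replaced by
#' bivariate normals pairing them with the observed per-participant EEG
#' slope measures (`EEG.mean`, `EEG.diff`), with correlations `rho_mean`
#' and `rho_diff` (`~ U(-1, 1)`, shared across groups or group-specific).
#' Participants lacking EEG contribute through the univariate marginals.
#'
#' @param trials Filtered trial tibble (columns `participant_id`, `group`,
#'   `difficulty` in easy/hard, `direction`, `response`, `rt_s`, `timeout`).
#' @param priors A [default_priors()] spec.
#' @param config A [de_config()].
#' @param s,deadline,penalty Likelihood constants (see [wfpt_loglik()]).
#' @param ages Optional named numeric vector of ages, one per participant.
#' @param slopes Optional tibble `participant_id`, `eeg_mean`, `eeg_diff`
#'   (from [extract_slopes()] or [simulate_slopes()]).
#' @param rho_variant `"shared"` (one correlation per pair across groups) or
#'   `"by_group"`.
#' @param eeg_priors A [default_eeg_priors()] spec (joint model only).
#' @param progress Print progress every 500 iterations.
#' @return An object of class `hddm_fit` (also `de_samples`): `draws`
#'   (iteration x chain x parameter, named), `par_names`, `accept`,
#'   `config`, `priors`, plus bookkeeping (`participants`, `groups`,
#'   `joint`, `age_adjusted`).
#' @export
fit_hddm <- function(trials, priors = default_priors(),
                     config = de_config(), s = 0.1, deadline = 2.5,
                     penalty = -1e10, ages = NULL, slopes = NULL,
                     rho_variant = c("shared", "by_group"),
                     eeg_priors = default_eeg_priors(),
                     progress = FALSE) {
  rho_variant <- match.arg(rho_variant)
  set.seed(config$seed)
  prep <- prepare_trials(trials)
  dat <- split_trials(prep)
  ids <- names(dat)
  P <- length(ids)
  C <- config$n_chains
  gsign <- vapply(dat, function(d) if (d$group == "dyslexia") 1 else -1,
                  numeric(1))
  joint <- !is.null(slopes)
  use_age <- !is.null(ages)
  age_c <- if (use_age) {
    if (!all(ids %in% names(ages))) stop("missing ages", call. = FALSE)
    a <- ages[ids]; a - mean(a)
  } else rep(0, P)

  eeg_mean <- rep(NA_real_, P); eeg_diff <- rep(NA_real_, P)
  if (joint) {
    i <- match(ids, slopes$participant_id)
    eeg_mean <- slopes$eeg_mean[i]
    eeg_diff <- slopes$eeg_diff[i]
    if (all(is.na(eeg_mean))) stop("no participants with EEG", call. = FALSE)
  }
  has_eeg <- !is.na(eeg_mean)
  n_rho <- if (!joint) 0L else if (rho_variant == "shared") 1L else 2L

  pn <- param_names()
  prior_rows <- lapply(seq_len(nrow(priors)), function(i) as.list(priors[i, ]))
  names(prior_rows) <- paste(priors$param, priors$hyper, sep = ".")
  eeg_rows <- lapply(seq_len(nrow(eeg_priors)),
                     function(i) as.list(eeg_priors[i, ]))
  names(eeg_rows) <- paste(eeg_priors$param, eeg_priors$hyper, sep = ".")

  # ---- state ----------------------------------------------------------
  th <- array(NA_real_, c(C, P, 5))     # subject params
  hy <- array(NA_real_, c(C, 5, 3))     # mu, sigma, delta per param
  ba <- matrix(0, C, 5)                 # age slopes
  ehy <- array(0, c(C, 2, 3))           # EEG.diff, EEG.mean triples
  rho <- matrix(0, C, max(1L, 2L * n_rho)) # [pair x group] columns

  min_rt <- vapply(dat, function(d) {
    r <- d$rt[!is.na(d$rt)]
    if (length(r)) min(r) else Inf
  }, numeric(1))

  draw_chain_state <- function() {
    h <- matrix(NA_real_, 5, 3)
    for (k in 1:5) {
      h[k, 1] <- prior_draw(prior_rows[[paste0(pn[k], ".mu")]])
      h[k, 2] <- prior_draw(prior_rows[[paste0(pn[k], ".sigma")]])
      h[k, 3] <- prior_draw(prior_rows[[paste0(pn[k], ".delta")]])
    }
    t_ <- matrix(NA_real_, P, 5)
    for (p in seq_len(P)) {
      loc <- h[, 1] + gsign[p] * h[, 3]
      t_[p, 1] <- rtnorm1(loc[1], h[1, 2], 0, Inf)
      t_[p, 2] <- rtnorm1(loc[2], h[2, 2], 0, 1)
      # non-decision time capped below the participant's fastest response:
      # a bare prior draw would exceed it with non-negligible probability
      # and strand the chain at the penalty floor
      cap <- min(min_rt[p] * 0.9, 1)
      t_[p, 3] <- runif(1, 0.5 * cap, 0.95 * cap)
      t_[p, 4] <- rnorm(1, loc[4], h[4, 2])
      t_[p, 5] <- rnorm(1, loc[5], h[5, 2])
    }
    list(h = h, t = t_)
  }

  # ---- component targets ---------------------------------------------
  loglik_p <- function(p, par5) {
    # par5: n x 5 in (a, z, ter, v.diff, v.mean) order
    ok <- par5[, 1] > 0 & par5[, 2] > 0 & par5[, 2] < 1 & par5[, 3] >= 0 &
      par5[, 3] < deadline
    out <- rep(-Inf, nrow(par5))
    if (any(ok)) {
      d <- dat[[p]]
      out[ok] <- wfpt_loglik_cpp(par5[ok, c(1, 2, 3, 5, 4), drop = FALSE],
                                 d$difficulty, d$dir_sign, d$response, d$rt,
                                 s, deadline, penalty)
    }
    out
  }

  # subject-density slice for parameter k over a subset of participants.
  # x: n x length(sub) matrix (chains rows, participants cols); hy_k: n x 3.
  bounds_k <- list(c(0, Inf), c(0, 1), c(0, Inf), c(-Inf, Inf), c(-Inf, Inf))
  slice_univ <- function(k, x, mu, sigma, delta, beta, gs, ac) {
    np <- length(gs)
    loc <- outer(mu, rep(1, np)) + outer(delta, gs) + outer(beta, ac)
    sg <- matrix(sigma, nrow = length(sigma), ncol = np)
    b <- bounds_k[[k]]
    if (is.finite(b[1]) || is.finite(b[2])) {
      dtnorm(x, loc, sg, b[1], b[2], log = TRUE)
    } else {
      dnorm(x, loc, sg, log = TRUE)
    }
  }

  # k = 4 pairs (v.diff, EEG.diff), k = 5 pairs (v.mean, EEG.mean):
  # bivariate normal for participants with EEG, univariate marginal for the
  # rest.  rh: n x 2 matrix of (typical, dyslexia) correlations.
  slice_k <- function(k, x, hy_k, beta, ehy_j, rh, sub = seq_len(P)) {
    gs <- gsign[sub]; ac <- age_c[sub]
    bad <- !(hy_k[, 2] > 0)
    sig <- hy_k[, 2]; sig[bad] <- NA # avoid sd<=0 warnings; rows masked below
    out <- slice_univ(k, x, hy_k[, 1], sig, hy_k[, 3], beta, gs, ac)
    if (joint && k >= 4) {
      e_obs <- (if (k == 4) eeg_diff else eeg_mean)[sub]
      idx <- which(!is.na(e_obs))
      bad <- bad | !(ehy_j[, 2] > 0) | abs(rh[, 1]) >= 1 | abs(rh[, 2]) >= 1
      if (length(idx)) {
        ni <- length(idx)
        esig <- ehy_j[, 2]; esig[!(esig > 0)] <- NA
        rh1 <- rh[, 1]; rh1[abs(rh1) >= 1] <- NA
        rh2 <- rh[, 2]; rh2[abs(rh2) >= 1] <- NA
        locv <- outer(hy_k[, 1], rep(1, ni)) + outer(hy_k[, 3], gs[idx]) +
          outer(beta, ac[idx])
        loce <- outer(ehy_j[, 1], rep(1, ni)) + outer(ehy_j[, 3], gs[idx])
        sv <- matrix(sig, nrow(out), ni)
        se <- matrix(esig, nrow(out), ni)
        rhm <- matrix(rh1, nrow(out), ni)
        dys <- gs[idx] > 0
        if (any(dys)) rhm[, dys] <- matrix(rh2, nrow(out), sum(dys))
        xe <- matrix(e_obs[idx], nrow(out), ni, byrow = TRUE)
        z1 <- (x[, idx, drop = FALSE] - locv) / sv
        z2 <- (xe - loce) / se
        q <- 1 - rhm^2
        ld <- -log(2 * pi) - log(sv) - log(se) - 0.5 * log(q) -
          (z1^2 - 2 * rhm * z1 * z2 + z2^2) / (2 * q)
        out[, idx] <- ld
      }
    }
    out[bad, ] <- -Inf
    out
  }

  rho_cols <- function(rh_mat, pair) {
    # expand stored rho matrix into (typical, dyslexia) columns for `pair`
    # ("diff" or "mean")
    if (!joint) return(matrix(0, C, 2))
    if (n_rho == 1L) {
      j <- if (pair == "diff") 1L else 2L
      cbind(rh_mat[, j], rh_mat[, j])
    } else {
      j <- if (pair == "diff") c(1L, 2L) else c(3L, 4L)
      rh_mat[, j, drop = FALSE]
    }
  }

  hyperprior_k <- function(k, hy_k) {
    prior_logdens(prior_rows[[paste0(pn[k], ".mu")]], hy_k[, 1]) +
      prior_logdens(prior_rows[[paste0(pn[k], ".sigma")]], hy_k[, 2]) +
      prior_logdens(prior_rows[[paste0(pn[k], ".delta")]], hy_k[, 3])
  }
  eeg_hyperprior_j <- function(j, e_j) {
    nmj <- c("EEG.diff", "EEG.mean")[j]
    prior_logdens(eeg_rows[[paste0(nmj, ".mu")]], e_j[, 1]) +
      prior_logdens(eeg_rows[[paste0(nmj, ".sigma")]], e_j[, 2]) +
      prior_logdens(eeg_rows[[paste0(nmj, ".delta")]], e_j[, 3])
  }

  # storage matrix of rho with named pairs
  if (joint) {
    rho <- matrix(0, C, if (n_rho == 1L) 2L else 4L)
  }

  # ---- initialisation -------------------------------------------------
  ll <- matrix(NA_real_, C, P)
  sdc <- array(NA_real_, c(C, P, 5))
  for (ci in seq_len(C)) {
    st <- draw_chain_state()
    llp <- numeric(P)
    for (p in seq_len(P)) {
      # re-draw one participant (not the whole chain) until their
      # likelihood is finite and clear of the out-of-support penalty
      ok <- FALSE
      for (att in 1:100) {
        llp[p] <- loglik_p(p, matrix(st$t[p, ], 1))
        if (is.finite(llp[p]) && llp[p] > penalty / 2) { ok <- TRUE; break }
        st2 <- draw_chain_state()
        st$t[p, ] <- st2$t[p, ]
      }
      if (!ok) stop("failed to initialise participant ", ids[p],
                    " in chain ", ci, " at a finite log posterior",
                    call. = FALSE)
    }
    ll[ci, ] <- llp
    hy[ci, , ] <- st$h
    th[ci, , ] <- st$t
    if (joint) {
      rho[ci, ] <- runif(ncol(rho), -0.3, 0.3)
      for (j in 1:2) {
        # moment-matched initialisation: without migration a chain whose
        # EEG location starts several prior SDs from the observed slope
        # scale can stall for the whole run
        nmj <- c("EEG.diff", "EEG.mean")[j]
        e_obs <- if (j == 1) eeg_diff[has_eeg] else eeg_mean[has_eeg]
        ehy[ci, j, 1] <- rnorm(1, mean(e_obs), sd(e_obs) / 2)
        ehy[ci, j, 2] <- sd(e_obs) * runif(1, 0.6, 1.4)
        ehy[ci, j, 3] <- prior_draw(eeg_rows[[paste0(nmj, ".delta")]])
      }
    }
  }
  for (k in 1:5) {
    rh <- rho_cols(rho, if (k == 4) "diff" else "mean")
    sdc[, , k] <- slice_k(k, th[, , k], hy[, k, ], ba[, k],
                          ehy[, if (k == 4) 1 else 2, ], rh)
  }

  # ---- proposal helper ------------------------------------------------
  propose <- function(cur) {
    nc <- nrow(cur); d <- ncol(cur)
    gam <- ifelse(runif(nc) < config$mode_jump_prob, 1,
                  config$gamma_scale * 2.38 / sqrt(2 * d))
    r1 <- integer(nc); r2 <- integer(nc)
    for (i in seq_len(nc)) {
      pick <- sample.int(nc - 1L, 2) # distinct, then shifted past self
      pick <- ifelse(pick >= i, pick + 1L, pick)
      r1[i] <- pick[1]; r2[i] <- pick[2]
    }
    cur + gam * (cur[r1, , drop = FALSE] - cur[r2, , drop = FALSE]) +
      matrix(runif(nc * d, -config$jitter, config$jitter), nc, d)
  }
  accept_mask <- function(dlp) {
    acc <- log(runif(length(dlp))) < dlp
    acc & !is.na(acc)
  }

  # ---- parameter naming / storage ------------------------------------
  par_names <- c()
  for (k in 1:5) par_names <- c(par_names, paste0(pn[k], "[", ids, "]"))
  # order: mu_a, sigma_a, delta_a, mu_z, ...
  hyper_names <- as.vector(vapply(pn, function(p)
    paste0(c("mu_", "sigma_", "delta_"), p), character(3)))
  par_names <- c(par_names, hyper_names)
  if (use_age) par_names <- c(par_names, paste0("beta_age_", pn))
  if (joint) {
    par_names <- c(par_names,
                   as.vector(vapply(c("EEG.diff", "EEG.mean"), function(p)
                     paste0(c("mu_", "sigma_", "delta_"), p), character(3))))
    rn <- if (n_rho == 1L) c("rho_diff", "rho_mean") else
      c("rho_diff_typical", "rho_diff_dyslexia",
        "rho_mean_typical", "rho_mean_dyslexia")
    par_names <- c(par_names, rn)
  }
  npar <- length(par_names)
  draws <- array(NA_real_, c(config$n_iter, C, npar),
                 dimnames = list(NULL, NULL, par_names))

  pack_state <- function() {
    out <- matrix(NA_real_, C, npar)
    j <- 0
    for (k in 1:5) { out[, j + seq_len(P)] <- th[, , k]; j <- j + P }
    for (k in 1:5) { out[, j + 1:3] <- hy[, k, ]; j <- j + 3 }
    if (use_age) { out[, j + 1:5] <- ba; j <- j + 5 }
    if (joint) {
      for (jj in 1:2) { out[, j + 1:3] <- ehy[, jj, ]; j <- j + 3 }
      out[, j + seq_len(ncol(rho))] <- rho
    }
    out
  }

  acc_subject <- 0; try_subject <- 0
  acc_hyper <- 0; try_hyper <- 0

  total_lp <- function() {
    lp <- rowSums(ll) + apply(sdc, 1, sum)
    for (k in 1:5) lp <- lp + hyperprior_k(k, hy[, k, ])
    if (use_age) lp <- lp + rowSums(dnorm(ba, 0, 0.5, log = TRUE))
    if (joint) {
      for (j in 1:2) lp <- lp + eeg_hyperprior_j(j, ehy[, j, ])
      # rho prior is U(-1,1): constant on support
    }
    lp
  }

  # ---- main loop ------------------------------------------------------
  for (it in seq_len(config$n_iter)) {
    if (config$migration_interval > 0 &&
        it >= config$migration_window[1] &&
        it <= config$migration_window[2] &&
        it %% config$migration_interval == 0) {
      lp <- total_lp()
      k <- sample.int(C, 1)
      set <- sample.int(C, k)
      donors <- c(set[k], set[-k])
      snap_th <- th[donors, , , drop = FALSE]
      snap_hy <- hy[donors, , , drop = FALSE]
      snap_ba <- ba[donors, , drop = FALSE]
      snap_ehy <- ehy[donors, , , drop = FALSE]
      snap_rho <- rho[donors, , drop = FALSE]
      snap_ll <- ll[donors, , drop = FALSE]
      snap_sdc <- sdc[donors, , , drop = FALSE]
      snap_lp <- lp[donors]
      for (j in seq_len(k)) {
        if (isTRUE(log(runif(1)) < snap_lp[j] - lp[set[j]])) {
          th[set[j], , ] <- snap_th[j, , ]
          hy[set[j], , ] <- snap_hy[j, , ]
          ba[set[j], ] <- snap_ba[j, ]
          ehy[set[j], , ] <- snap_ehy[j, , ]
          rho[set[j], ] <- snap_rho[j, ]
          ll[set[j], ] <- snap_ll[j, ]
          sdc[set[j], , ] <- snap_sdc[j, , ]
          lp[set[j]] <- snap_lp[j]
        }
      }
    }

    # subject blocks
    for (p in seq_len(P)) {
      cur <- th[, p, ]
      prop <- propose(cur)
      ll_new <- loglik_p(p, prop)
      sd_new <- matrix(NA_real_, C, 5)
      for (k in 1:5) {
        rh <- rho_cols(rho, if (k == 4) "diff" else "mean")
        sd_new[, k] <- slice_k(k, prop[, k, drop = FALSE], hy[, k, ],
                               ba[, k], ehy[, if (k == 4) 1 else 2, ],
                               rh, sub = p)[, 1]
      }
      dlp <- ll_new + rowSums(sd_new) - ll[, p] - rowSums(sdc[, p, ])
      acc <- accept_mask(dlp)
      th[acc, p, ] <- prop[acc, ]
      ll[acc, p] <- ll_new[acc]
      sdc[acc, p, ] <- sd_new[acc, ]
      acc_subject <- acc_subject + sum(acc); try_subject <- try_subject + C
    }

    # hyperparameter triples
    for (k in 1:5) {
      cur <- hy[, k, ]
      prop <- propose(cur)
      rh <- rho_cols(rho, if (k == 4) "diff" else "mean")
      sl_new <- slice_k(k, th[, , k], prop, ba[, k],
                        ehy[, if (k == 4) 1 else 2, ], rh)
      dlp <- rowSums(sl_new) + hyperprior_k(k, prop) -
        rowSums(sdc[, , k]) - hyperprior_k(k, cur)
      acc <- accept_mask(dlp)
      hy[acc, k, ] <- prop[acc, ]
      sdc[acc, , k] <- sl_new[acc, ]
      acc_hyper <- acc_hyper + sum(acc); try_hyper <- try_hyper + C
    }

    # age-slope blocks
    if (use_age) {
      for (k in 1:5) {
        cur <- ba[, k, drop = FALSE]
        prop <- propose(cur)
        rh <- rho_cols(rho, if (k == 4) "diff" else "mean")
        sl_new <- slice_k(k, th[, , k], hy[, k, ], prop[, 1],
                          ehy[, if (k == 4) 1 else 2, ], rh)
        dlp <- rowSums(sl_new) + dnorm(prop[, 1], 0, 0.5, log = TRUE) -
          rowSums(sdc[, , k]) - dnorm(ba[, k], 0, 0.5, log = TRUE)
        acc <- accept_mask(dlp)
        ba[acc, k] <- prop[acc, 1]
        sdc[acc, , k] <- sl_new[acc, ]
      }
    }

    # EEG hyper triples and correlation blocks
    if (joint) {
      for (j in 1:2) {
        k <- if (j == 1) 4L else 5L
        cur <- ehy[, j, ]
        prop <- propose(cur)
        rh <- rho_cols(rho, if (k == 4) "diff" else "mean")
        sl_new <- slice_k(k, th[, , k], hy[, k, ], ba[, k], prop, rh)
        dlp <- rowSums(sl_new) + eeg_hyperprior_j(j, prop) -
          rowSums(sdc[, , k]) - eeg_hyperprior_j(j, cur)
        acc <- accept_mask(dlp)
        ehy[acc, j, ] <- prop[acc, ]
        sdc[acc, , k] <- sl_new[acc, ]
      }
      for (rc in seq_len(ncol(rho))) {
        cur <- rho[, rc, drop = FALSE]
        prop <- propose(cur)
        # reflect at the U(-1,1) boundaries (symmetric proposal preserved)
        pv <- prop[, 1]
        pv <- ifelse(pv > 1, 2 - pv, ifelse(pv < -1, -2 - pv, pv))
        pv <- pmin(pmax(pv, -1 + 1e-9), 1 - 1e-9)
        rho_new <- rho; rho_new[, rc] <- pv
        pair <- if (n_rho == 1L) c("diff", "mean")[rc] else
          c("diff", "diff", "mean", "mean")[rc]
        k <- if (pair == "diff") 4L else 5L
        rh <- rho_cols(rho_new, pair)
        sl_new <- slice_k(k, th[, , k], hy[, k, ], ba[, k],
                          ehy[, if (k == 4) 1 else 2, ], rh)
        dlp <- rowSums(sl_new) - rowSums(sdc[, , k])
        acc <- accept_mask(dlp)
        rho[acc, rc] <- pv[acc]
        sdc[acc, , k] <- sl_new[acc, ]
      }
    }

    draws[it, , ] <- pack_state()
    if (progress && it %% 500 == 0) {
      message("iteration ", it, "/", config$n_iter)
    }
  }

  structure(list(draws = draws, par_names = par_names,
                 accept = c(subject = acc_subject / max(1, try_subject),
                            hyper = acc_hyper / max(1, try_hyper)),
                 config = config, priors = priors,
                 eeg_priors = if (joint) eeg_priors else NULL,
                 participants = ids, groups = gsign,
                 joint = joint, rho_variant = if (joint) rho_variant else NA,
                 age_adjusted = use_age,
                 s = s, deadline = deadline),
            class = c("hddm_fit", "de_samples"))
}
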