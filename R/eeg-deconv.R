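#' Epoch and baseline continuous EEG
#'
#' Cuts response-locked epochs (default -600..200 ms around each response)
#' from a continuous recording and subtracts, channel-wise per trial, the
#' mean of the baseline interval: the last 100 ms of the random-motion
#' period, i.e. the 100 ms immediately before the stimulus onset that the
#' response belongs to. Epochs whose window (or baseline) falls outside the
#' recording are dropped and counted.
#'
#' @param rec An `eeg_recording` (see [simulate_eeg()]), or a list with
#'   `data` (channels x samples), `fs` and `events`.
#' @param window Epoch window in seconds relative to the lock event.
#' @param lock Event type to lock to (`"response"` or `"stimulus"`).
#' @param baseline_ms Length of the pre-stimulus baseline interval, ms.
#' @return A list of class `epoch_set`: `data` (trials x channels x time),
#'   `times` (seconds relative to lock), `difficulty` (per trial),
#'   `n_dropped`.
#' @export
epoch_and_baseline <- function(rec, window = c(-0.6, 0.2),
                               lock = "response", baseline_ms = 100) {
  fs <- rec$fs
  ev <- rec$events
  locks <- ev[ev$type == lock, ]
  stims <- ev[ev$type == "stimulus", ]
  ns <- ncol(rec$data)
  nch <- nrow(rec$data)
  rel <- seq(round(window[1] * fs), round(window[2] * fs))
  times <- rel / fs
  nb <- round(baseline_ms / 1000 * fs)

  keep <- list(); diffs <- character(); dropped <- 0L
  for (i in seq_len(nrow(locks))) {
    t0 <- locks$time_s[i]
    # the stimulus this lock event belongs to (latest stimulus at/before it)
    before <- stims$time_s[stims$time_s <= t0 + 1e-9]
    if (!length(before)) { dropped <- dropped + 1L; next }
    st <- max(before)
    c0 <- round(t0 * fs) + 1L
    idx <- c0 + rel
    sb <- round(st * fs) + 1L
    bidx <- (sb - nb):(sb - 1L)
    if (min(idx, bidx) < 1L || max(idx, bidx) > ns) {
      dropped <- dropped + 1L; next
    }
    seg <- rec$data[, idx, drop = FALSE]
    bl <- rowMeans(rec$data[, bidx, drop = FALSE])
    keep[[length(keep) + 1L]] <- seg - bl
    diffs <- c(diffs, locks$difficulty[i])
  }
  if (!length(keep)) stop("no resolvable epochs", call. = FALSE)
  data <- array(NA_real_, c(length(keep), nch, length(rel)))
  for (i in seq_along(keep)) data[i, , ] <- keep[[i]]
  structure(list(data = data, times = times, difficulty = diffs,
                 n_dropped = dropped, fs = fs),
            class = "epoch_set")
}

#' Reliable Components Analysis
#'
#' Spatial filtering that maximises trial-to-trial reliability: weights w
#' maximise the ratio of the across-trials cross-covariance (the average
#' covariance between distinct trials' time courses) to the within-trial
#' covariance, solved as a generalized eigendecomposition. Components are
#' ordered by their reliability coefficient (the generalized eigenvalue);
#' forward-model projections are computed by mapping the weights through
#' the pooled data covariance, and each component's sign is fixed so the
#' largest-magnitude entry of its forward projection is positive.
#' Rank-deficient within-trial covariance is handled by diagonal loading
#' with a warning.
#'
#' @param epochs An `epoch_set` (possibly pooled over participants via
#'   [pool_epochs()]), or a trials x channels x time array.
#' @param n_components Components to return (default all).
#' @return A list of class `rca_model`: `weights` (channels x components,
#'   unit-norm columns), `forward` (channels x components), `reliability`
#'   (non-increasing).
#' @export
rca_fit <- function(epochs, n_components = NULL) {
  data <- if (inherits(epochs, "epoch_set")) epochs$data else epochs
  stopifnot(length(dim(data)) == 3)
  n_tr <- dim(data)[1]; nch <- dim(data)[2]; nt <- dim(data)[3]
  if (n_tr < 2) stop("RCA needs at least 2 trials", call. = FALSE)
  if (nch < 2) stop("RCA needs at least 2 channels", call. = FALSE)

  # demean each trial's channel time courses, then accumulate
  Rw <- matrix(0, nch, nch)
  Ssum <- matrix(0, nch, nt)
  for (i in seq_len(n_tr)) {
    X <- data[i, , , drop = TRUE]
    if (nch == 1) X <- matrix(X, 1)
    X <- X - rowMeans(X)
    Rw <- Rw + X %*% t(X)
    Ssum <- Ssum + X
  }
  Rtot <- Ssum %*% t(Ssum)
  Rb <- (Rtot - Rw) / (n_tr * (n_tr - 1))   # mean cross-trial covariance
  Rw <- Rw / n_tr                           # mean within-trial covariance

  ev <- eigen(Rw, symmetric = TRUE)
  tol <- max(ev$values) * 1e-10
  if (any(ev$values < tol)) {
    warning("within-trial covariance is rank deficient; applying diagonal ",
            "loading")
    Rw <- Rw + diag(max(ev$values) * 1e-6, nch)
    ev <- eigen(Rw, symmetric = TRUE)
  }
  # whiten, then ordinary symmetric eigenproblem
  Wh <- ev$vectors %*% diag(1 / sqrt(ev$values)) %*% t(ev$vectors)
  M <- Wh %*% Rb %*% Wh
  M <- (M + t(M)) / 2
  eg <- eigen(M, symmetric = TRUE)
  W <- Wh %*% eg$vectors
  rel_coef <- eg$values
  # unit-norm weights, reliability order is already non-increasing
  W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  # forward projections: data covariance mapped through the filters
  A <- Rw %*% W %*% solve(t(W) %*% Rw %*% W)
  sgn <- apply(A, 2, function(col) sign(col[which.max(abs(col))]))
  sgn[sgn == 0] <- 1
  W <- sweep(W, 2, sgn, "*")
  A <- sweep(A, 2, sgn, "*")
  k <- n_components %||% nch
  structure(list(weights = W[, seq_len(k), drop = FALSE],
                 forward = A[, seq_len(k), drop = FALSE],
                 reliability = rel_coef[seq_len(k)]),
            class = "rca_model")
}

#' @rdname rca_fit
#' @param epoch_list List of `epoch_set` objects to pool (stacked along the
#'   trial dimension; channel counts must agree).
#' @export
pool_epochs <- function(epoch_list) {
  datas <- lapply(epoch_list, function(e) e$data)
  nch <- dim(datas[[1]])[2]; nt <- dim(datas[[1]])[3]
  data <- array(NA_real_, c(sum(vapply(datas, function(d) dim(d)[1], 0L)),
                            nch, nt))
  i <- 0L
  for (d in datas) {
    data[i + seq_len(dim(d)[1]), , ] <- d
    i <- i + dim(d)[1]
  }
  structure(list(data = data, times = epoch_list[[1]]$times,
                 difficulty = unlist(lapply(epoch_list,
                                            function(e) e$difficulty)),
                 n_dropped = sum(vapply(epoch_list,
                                        function(e) e$n_dropped, 0L)),
                 fs = epoch_list[[1]]$fs),
            class = "epoch_set")
}

#' Project continuous data through a spatial filter
#'
#' @param rec An `eeg_recording`.
#' @param rca An `rca_model` (or a numeric weight vector).
#' @param component Which component's weights to use.
#' @return The recording with `data` replaced by the 1 x samples component
#'   waveform.
#' @export
rca_project <- function(rec, rca, component = 1) {
  w <- if (is.numeric(rca)) rca else rca$weights[, component]
  rec$data <- matrix(as.numeric(t(w) %*% rec$data), nrow = 1)
  rec
}

#' Time-expanded FIR design matrix
#'
#' Builds the sparse deconvolution design: one boxcar predictor per (event
#' type, difficulty, lag) over a half-open lag window (default [-1000,
#' 1000) ms), so that at 250 Hz each event type x difficulty contributes
#' exactly 500 lag predictors. Event times are snapped to the nearest
#' sample. Rows are recording samples; a row has one nonzero per event
#' whose lag window covers it.
#'
#' @param events Event tibble (`time_s`, `type`, `difficulty`); `catch`
#'   difficulty is treated as `easy` (catch stimuli are maximal-coherence
#'   probes of the same kind).
#' @param fs Sampling rate, Hz.
#' @param n_samples Number of rows (samples in the recording).
#' @param window Lag window in seconds, half-open on the right.
#' @return A list of class `fir_design`: `X` (sparse `dgCMatrix`), `cols`
#'   (tibble `event_type`, `difficulty`, `lag_s` per column), `fs`.
#' @export
build_design <- function(events, fs, n_samples, window = c(-1, 1)) {
  if (nrow(events) == 0) stop("empty event list", call. = FALSE)
  ev <- events
  ev$difficulty[ev$difficulty == "catch"] <- "easy"
  lags <- seq(round(window[1] * fs), round(window[2] * fs) - 1L)
  conds <- tidyr::expand_grid(event_type = c("stimulus", "response"),
                              difficulty = c("easy", "hard"))
  cols <- tidyr::expand_grid(conds, lag_idx = lags) |>
    dplyr::mutate(lag_s = .data$lag_idx / fs,
                  col = dplyr::row_number())
  nlag <- length(lags)
  ii <- integer(0); jj <- integer(0)
  for (ci in seq_len(nrow(conds))) {
    sel <- ev$type == conds$event_type[ci] &
      ev$difficulty == conds$difficulty[ci]
    if (!any(sel)) next
    smp <- round(ev$time_s[sel] * fs) + 1L
    rows <- rep(smp, each = nlag) + rep(lags, times = sum(sel))
    colid <- rep((ci - 1L) * nlag + seq_len(nlag), times = sum(sel))
    ok <- rows >= 1L & rows <= n_samples
    ii <- c(ii, rows[ok]); jj <- c(jj, colid[ok])
  }
  X <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                            dims = c(n_samples, nrow(cols)))
  structure(list(X = X,
                 cols = dplyr::select(cols, "event_type", "difficulty",
                                      "lag_s"),
                 fs = fs, window = window),
            class = "fir_design")
}

#' Sliding-window artifact mask
#'
#' Marks for exclusion every sample of any sliding segment (default 2000 ms
#' long, advancing in 100 ms steps) that contains an amplitude beyond the
#' threshold (default +/- 250 microvolts). Excluded samples are removed
#' from the deconvolution fit.
#'
#' @param x Numeric component waveform (microvolts).
#' @param fs Sampling rate, Hz.
#' @param threshold Absolute amplitude threshold, microvolts.
#' @param segment_s,step_s Sliding segment length and step, seconds.
#' @return A list: `mask` (logical, TRUE = excluded), `fraction` excluded.
#' @export
mask_artifacts <- function(x, fs, threshold = 250, segment_s = 2,
                           step_s = 0.1) {
  n <- length(x)
  seg <- round(segment_s * fs)
  step <- round(step_s * fs)
  bad <- abs(x) > threshold
  mask <- logical(n)
  if (any(bad)) {
    starts <- seq(1L, max(1L, n - seg + 1L), by = step)
    for (s0 in starts) {
      idx <- s0:min(n, s0 + seg - 1L)
      if (any(bad[idx])) mask[idx] <- TRUE
    }
  }
  list(mask = mask, fraction = mean(mask))
}

#' FIR deconvolution by (ridge) regression
#'
#' Solves `beta = argmin ||y - X beta||^2 + lambda ||beta||^2` for the
#' time-expanded design, unmixing overlapping stimulus- and response-locked
#' activity; `lambda = 0` is ordinary least squares (an error names the
#' ridge path if the design is singular). Masked samples are dropped from
#' both sides before solving.
#'
#' @param design An `fir_design`.
#' @param y Continuous component waveform (length = design rows).
#' @param lambda Ridge penalty (>= 0).
#' @param mask Optional logical exclusion mask (TRUE = drop sample).
#' @return A list of class `deconv_erp`: `betas` (tibble `event_type`,
#'   `difficulty`, `lag_s`, `beta` in microvolts), `lambda`, `fs`, plus
#'   `gcv` diagnostics.
#' @export
deconvolve <- function(design, y, lambda = 0, mask = NULL) {
  if (lambda < 0) stop("`lambda` must be >= 0", call. = FALSE)
  X <- design$X
  if (!is.null(mask)) {
    X <- X[!mask, , drop = FALSE]
    y <- y[!mask]
  }
  keep <- Matrix::colSums(X) > 0 # lags never observed stay at 0
  XtX <- as.matrix(Matrix::crossprod(X[, keep, drop = FALSE]))
  Xty <- as.numeric(Matrix::crossprod(X[, keep, drop = FALSE], y))
  A <- XtX + diag(lambda, ncol(XtX))
  beta_k <- tryCatch(solve(A, Xty), error = function(e) {
    if (lambda == 0) {
      stop("design is singular at lambda = 0; use ridge regularisation ",
           "(lambda > 0)", call. = FALSE)
    }
    stop(e)
  })
  beta <- numeric(ncol(design$X))
  beta[keep] <- beta_k
  structure(list(betas = dplyr::mutate(design$cols, beta = beta),
                 lambda = lambda, fs = design$fs),
            class = "deconv_erp")
}

#' Cross-validated common ridge penalty
#'
#' Finds each participant's best ridge penalty by k-fold cross-validation
#' over contiguous time segments (minimising held-out MSE on the grid),
#' then returns the mode across participants — the constrained common
#' penalty applied to everyone so that differences in regularisation
#' cannot masquerade as group differences in the deconvolved waveforms.
#' Ties in the mode resolve to the smaller penalty.
#'
#' @param fits List with one element per participant: `design`
#'   (`fir_design`), `y`, and optionally `mask`.
#' @param grid Candidate penalties (default 0, 0.5, ..., 30).
#' @param k Folds (default 5, contiguous segments).
#' @return A list: `lambda` (the common modal penalty), `per_participant`
#'   (tibble `participant`, `lambda_best`), `cv` (long tibble of held-out
#'   MSE).
#' @export
select_lambda <- function(fits, grid = seq(0, 30, by = 0.5), k = 5) {
  if (length(grid) < 1) stop("empty lambda grid", call. = FALSE)
  if (k < 2) stop("need at least 2 folds", call. = FALSE)
  cv_all <- purrr::imap_dfr(fits, function(f, nm) {
    X <- f$design$X; y <- f$y
    if (!is.null(f$mask)) { X <- X[!f$mask, , drop = FALSE]; y <- y[!f$mask] }
    n <- nrow(X)
    fold <- cut(seq_len(n), breaks = k, labels = FALSE)
    keep <- Matrix::colSums(X) > 0
    X <- X[, keep, drop = FALSE]
    mse <- matrix(NA_real_, k, length(grid))
    for (fi in seq_len(k)) {
      tr <- fold != fi
      Xt <- X[tr, , drop = FALSE]; yt <- y[tr]
      Xv <- X[!tr, , drop = FALSE]; yv <- y[!tr]
      XtX <- as.matrix(Matrix::crossprod(Xt))
      Xty <- as.numeric(Matrix::crossprod(Xt, yt))
      eg <- eigen(XtX, symmetric = TRUE) # one decomposition per fold,
      ev <- pmax(eg$values, 0)           # then the whole lambda path is cheap
      Uty <- as.numeric(t(eg$vectors) %*% Xty)
      for (gi in seq_along(grid)) {
        d <- ev + grid[gi]
        if (any(d <= 0)) { mse[fi, gi] <- Inf; next }
        beta <- eg$vectors %*% (Uty / d)
        pred <- as.numeric(Xv %*% beta)
        mse[fi, gi] <- mean((yv - pred)^2)
      }
    }
    tibble::tibble(participant = nm, lambda = rep(grid, each = k),
                   fold = rep(seq_len(k), length(grid)),
                   mse = as.numeric(mse))
  })
  per <- cv_all |>
    dplyr::group_by(.data$participant, .data$lambda) |>
    dplyr::summarise(mse = mean(.data$mse), .groups = "drop_last") |>
    dplyr::slice_min(.data$mse, n = 1, with_ties = FALSE) |>
    dplyr::summarise(lambda_best = .data$lambda, .groups = "drop")
  tab <- table(per$lambda_best)
  modal <- as.numeric(names(tab)[tab == max(tab)])
  list(lambda = min(modal), per_participant = per, cv = cv_all)
}

#' Pre-response slope of the deconvolved waveform
#'
#' Fits an OLS regression line to each difficulty level's response-locked
#' deconvolved waveform over the window from -200 ms to 0 ms around the
#' response (inclusive), in microvolts per second — the build-up rate of
#' the centro-parietal component. Aggregates: `eeg_mean` is the mean of
#' the two slopes and `eeg_diff` their difference (easy - hard), mirroring
#' the drift-rate parameterisation.
#'
#' @param erp A `deconv_erp`.
#' @param window Slope window in seconds relative to the response.
#' @return A tibble: `slope_easy`, `slope_hard` (microvolt/s), `eeg_mean`,
#'   `eeg_diff`.
#' @export
extract_slopes <- function(erp, window = c(-0.2, 0)) {
  b <- erp$betas[erp$betas$event_type == "response", ]
  sel <- b$lag_s >= window[1] - 1e-9 & b$lag_s <= window[2] + 1e-9
  if (!any(sel)) stop("slope window not covered by the lag axis",
                      call. = FALSE)
  slope_of <- function(diffic) {
    bb <- b[sel & b$difficulty == diffic, ]
    unname(coef(lm(bb$beta ~ bb$lag_s))[2])
  }
  se <- slope_of("easy"); sh <- slope_of("hard")
  tibble::tibble(slope_easy = se, slope_hard = sh,
                 eeg_mean = (se + sh) / 2, eeg_diff = se - sh)
}
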