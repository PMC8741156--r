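# epoching, RCA, FIR design, artifact mask, ridge deconvolution, slopes

noiseless_rec <- function(n = 2, blocks = 1, seed = 51, nch = 1) {
  g <- generator_config(noise_sd = 0, n_channels = nch)
  sim <- tiny_sim(n = n, blocks = blocks, seed = seed, config = g)
  sim$subjects <- simulate_slopes(sim$subjects, g, seed = seed)
  list(recs = simulate_eeg(sim, g, seed = seed), sim = sim, g = g)
}

test_that("baselining removes per-trial DC offsets exactly", {
  x <- noiseless_rec()
  rec <- x$recs[[1]]
  # plant a distinct DC offset over each trial's pre-stimulus + epoch span
  stims <- rec$events$time_s[rec$events$type == "stimulus"]
  for (i in seq_along(stims)) {
    i0 <- round((stims[i] - 0.2) * rec$fs)
    i1 <- min(ncol(rec$data), i0 + 3 * rec$fs)
    rec$data[, i0:i1] <- rec$data[, i0:i1] + i * 7
  }
  ep0 <- epoch_and_baseline(x$recs[[1]])
  ep1 <- epoch_and_baseline(rec)
  expect_equal(ep1$data, ep0$data, tolerance = 1e-9)
  # a constant channel baselines to exactly zero
  rec2 <- x$recs[[1]]
  rec2$data[] <- 42
  ep2 <- epoch_and_baseline(rec2)
  expect_true(all(ep2$data == 0))
})

test_that("epochs at the recording boundary are dropped and counted", {
  x <- noiseless_rec()
  rec <- x$recs[[1]]
  n_resp <- sum(rec$events$type == "response")
  # truncate the recording so the last response's window runs off the end
  last_resp <- max(rec$events$time_s[rec$events$type == "response"])
  rec$data <- rec$data[, seq_len(round((last_resp + 0.1) * rec$fs)),
                       drop = FALSE]
  ep <- epoch_and_baseline(rec)
  expect_equal(dim(ep$data)[1] + ep$n_dropped, n_resp)
  expect_gte(ep$n_dropped, 1L)
})

test_that("RCA recovers a planted topography and ranks noise near zero", {
  set.seed(52)
  nch <- 32; nt <- 100; ntime <- 120
  topo <- exp(-seq(-2, 2, length.out = nch)^2)
  topo <- topo / sqrt(sum(topo^2))
  wave <- 3 * sin(seq(0, 4 * pi, length.out = ntime))
  dat <- array(0, c(nt, nch, ntime))
  for (i in seq_len(nt)) {
    dat[i, , ] <- outer(topo, wave) + matrix(rnorm(nch * ntime), nch)
  }
  m <- rca_fit(dat)
  expect_gt(abs(cor(m$weights[, 1], topo)), 0.95)
  expect_true(all(diff(m$reliability) <= 1e-9))
  expect_equal(sum(m$weights[, 1]^2), 1, tolerance = 1e-9)
  # sign convention: dominant forward-projection entry positive
  expect_gt(m$forward[which.max(abs(m$forward[, 1])), 1], 0)

  # duplicating every trial leaves the leading filter unchanged up to sign
  dat2 <- array(0, c(2 * nt, nch, ntime))
  dat2[seq_len(nt), , ] <- dat; dat2[nt + seq_len(nt), , ] <- dat
  m2 <- rca_fit(dat2)
  expect_gt(abs(cor(m2$weights[, 1], m$weights[, 1])), 0.9999)

  # pure noise: top reliability below the 95th percentile of a
  # trial-shuffled null
  noise <- array(rnorm(60 * 16 * 80), c(60, 16, 80))
  mn <- rca_fit(noise)
  null_top <- vapply(1:19, function(r) {
    shuf <- noise[sample(60), , ]
    for (i in 1:60) shuf[i, , ] <- shuf[i, , sample(80)]
    rca_fit(shuf)$reliability[1]
  }, numeric(1))
  expect_lt(mn$reliability[1], max(null_top) * 1.5)
  expect_lt(mn$reliability[1], 0.1)
})

test_that("the time-expanded design has 500 lags per event type and
           difficulty at 250 Hz", {
  ev <- tibble::tibble(time_s = c(10, 10.7, 14, 14.9),
                       type = c("stimulus", "response", "stimulus",
                                "response"),
                       difficulty = c("easy", "easy", "hard", "hard"))
  des <- build_design(ev, fs = 250, n_samples = 5000)
  expect_equal(ncol(des$X), 2000L)
  expect_equal(nrow(des$cols), 2000L)
  counts <- dplyr::count(des$cols, event_type, difficulty)
  expect_true(all(counts$n == 500L))
  # half-open window: lags span [-1000, 996] ms
  expect_equal(range(des$cols$lag_s), c(-1, 0.996))

  # single isolated event: its rows form a shifted identity pattern
  ev1 <- tibble::tibble(time_s = 10, type = "stimulus", difficulty = "easy")
  d1 <- build_design(ev1, fs = 250, n_samples = 5000)
  sub <- d1$X[round(10 * 250) + 1 + (-250:249), 1:500]
  expect_equal(as.numeric(Matrix::diag(sub)), rep(1, 500))
  expect_equal(sum(d1$X), 500)

  # two same-condition events 100 ms apart: overlap rows have 2 nonzeros
  ev2 <- tibble::tibble(time_s = c(10, 10.1), type = "stimulus",
                        difficulty = "easy")
  d2 <- build_design(ev2, fs = 250, n_samples = 5000)
  rs <- Matrix::rowSums(d2$X)
  overlap <- round(10.1 * 250) + 1 + (-250):(249 - 25)
  expect_true(all(rs[overlap] == 2))
  expect_error(build_design(ev2[0, ], 250, 100), "empty")
})

test_that("artifact masking excludes whole sliding segments around
           excursions", {
  fs <- 250
  x <- rep(0, 20 * fs)
  expect_equal(mask_artifacts(x, fs)$fraction, 0)

  x[10 * fs] <- 300  # single spike above threshold
  m <- mask_artifacts(x, fs)
  expect_gte(sum(m$mask), 2 * fs)          # at least one full 2 s segment
  expect_true(m$mask[10 * fs])
  # samples well away from the spike survive
  expect_false(any(m$mask[1:(7 * fs)]))

  # spikes occupying a known stretch: excluded fraction matches to within
  # one segment's granularity
  x2 <- rep(0, 100 * fs)
  x2[seq(40 * fs, 45 * fs)] <- 400
  m2 <- mask_artifacts(x2, fs)
  expect_lt(abs(m2$fraction - (5 + 2 + 2) / 100), 2.2 / 100)
})

test_that("noiseless deconvolution recovers planted kernels exactly and
           ridge shrinks monotonically", {
  x <- noiseless_rec(n = 1, blocks = 2)
  rec <- x$recs[[1]]
  y <- as.numeric(rec$data[1, ])
  des <- build_design(rec$events, rec$fs, length(y))
  erp <- deconvolve(des, y, lambda = 0)
  b <- erp$betas[erp$betas$event_type == "stimulus" &
                   erp$betas$difficulty == "easy", ]
  sk <- stim_kernel_wave(x$g, "easy")
  got <- b$beta[b$lag_s >= 0 & b$lag_s < 0.6 - 1e-9]
  expect_equal(got, sk$amplitude, tolerance = 1e-6)
  expect_gt(cor(b$beta[match(round(sk$lag_s * 250), round(b$lag_s * 250))],
                sk$amplitude), 0.99)

  # lambda -> infinity drives ||beta|| to zero monotonically
  norms <- vapply(c(0, 1, 10, 100, 1e4, 1e6), function(l)
    sum(deconvolve(des, y, lambda = l)$betas$beta^2), numeric(1))
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[6] / norms[1], 1e-3)
  expect_error(deconvolve(des, y, lambda = -1), "lambda")
})

test_that("deconvolution reduces to the trial-average ERP when events never
           overlap", {
  fs <- 250
  kern <- 2 * sin(pi * seq(0, 0.6 - 1 / fs, by = 1 / fs) / 0.6)
  times <- seq(5, 120, by = 5)  # far beyond the 2 s lag span
  n <- 125 * fs
  y <- rep(0, n)
  for (t0 in times) {
    i0 <- round(t0 * fs) + 1
    y[i0 + seq_along(kern) - 1] <- y[i0 + seq_along(kern) - 1] + kern
  }
  ev <- tibble::tibble(time_s = times, type = "stimulus",
                       difficulty = "easy")
  des <- build_design(ev, fs, n)
  erp <- deconvolve(des, y, lambda = 0)
  b <- erp$betas[erp$betas$event_type == "stimulus" &
                   erp$betas$difficulty == "easy", ]
  # trial-average ERP over the same lag axis
  avg <- vapply(round(b$lag_s * fs), function(l)
    mean(y[round(times * fs) + 1 + l]), numeric(1))
  expect_lt(max(abs(b$beta - avg)), 1e-6)
})

test_that("singular OLS designs direct the user to ridge", {
  ev <- tibble::tibble(time_s = c(10, 10.004), type = "stimulus",
                       difficulty = c("easy", "hard"))
  des <- build_design(ev, 250, 3000)
  y <- rnorm(3000)
  expect_error(deconvolve(des, y, lambda = 0), "ridge")
  expect_silent(deconvolve(des, y, lambda = 1))
})

test_that("cross-validated penalties hit the grid edges in the limiting
           cases and the common value is the mode", {
  set.seed(53)
  fs <- 100
  mk <- function(noise) {
    times <- seq(2, 38, by = 2.5)
    n <- 40 * fs
    y <- rnorm(n, 0, noise)
    kern <- sin(pi * seq(0, 0.5, by = 1 / fs) / 0.5)
    for (t0 in times) {
      i0 <- round(t0 * fs) + 1
      y[i0 + seq_along(kern) - 1] <- y[i0 + seq_along(kern) - 1] + kern
    }
    ev <- tibble::tibble(time_s = times, type = "stimulus",
                         difficulty = "easy")
    list(design = build_design(ev, fs, n, window = c(-0.2, 0.8)), y = y)
  }
  grid <- c(0, 2, 5, 10, 20)
  # pure noise favours maximal shrinkage; a clean signal favours none
  pure_noise <- list(p1 = list(design = mk(1)$design, y = rnorm(40 * fs)))
  expect_equal(select_lambda(pure_noise, grid = grid, k = 4)$lambda, 20)
  clean <- list(p1 = mk(0))
  expect_equal(select_lambda(clean, grid = grid, k = 4)$lambda, 0)
  # mode across participants: two noisy, one clean
  sel <- select_lambda(list(a = list(design = mk(2)$design,
                                     y = rnorm(40 * fs, 0, 2)),
                            b = list(design = mk(2)$design,
                                     y = rnorm(40 * fs, 0, 2)),
                            c = mk(0)),
                       grid = grid, k = 4)
  expect_equal(sel$lambda, 20)
  expect_equal(nrow(sel$per_participant), 3L)
})

test_that("slope extraction is exact on ramps and unbiased under noise", {
  lag <- seq(-1, 0.996, by = 0.004)
  mk_erp <- function(wave_easy, wave_hard) {
    cols <- tidyr::expand_grid(event_type = c("stimulus", "response"),
                               difficulty = c("easy", "hard"),
                               lag_s = lag)
    cols$beta <- 0
    sel_e <- cols$event_type == "response" & cols$difficulty == "easy"
    sel_h <- cols$event_type == "response" & cols$difficulty == "hard"
    cols$beta[sel_e] <- wave_easy
    cols$beta[sel_h] <- wave_hard
    structure(list(betas = cols, lambda = 0, fs = 250),
              class = "deconv_erp")
  }
  # ramp rising 1 uV over the final 200 ms: slope 5 uV/s
  ramp <- pmax(0, (lag + 0.2) / 0.2)
  sl <- extract_slopes(mk_erp(ramp, ramp * 0))
  expect_equal(sl$slope_easy, 5, tolerance = 1e-9)
  expect_equal(sl$slope_hard, 0, tolerance = 1e-9)
  expect_equal(sl$eeg_mean, 2.5, tolerance = 1e-9)
  expect_equal(sl$eeg_diff, 5, tolerance = 1e-9)

  # noisy ramps: estimates unbiased within 3 SEs over 100 replicates
  set.seed(54)
  ests <- vapply(1:100, function(i)
    extract_slopes(mk_erp(ramp + rnorm(length(lag), 0, 0.1),
                          ramp * 0))$slope_easy, numeric(1))
  expect_lt(abs(mean(ests) - 5), 3 * sd(ests) / sqrt(100))
  expect_error(extract_slopes(mk_erp(ramp, ramp), window = c(-3, -2.5)),
               "window")
})

test_that("the slope pipeline recovers planted slopes and the drift-slope
           correlation", {
  g <- generator_config(noise_sd = 0)
  d <- study_design(n_per_group = 4, blocks_per_task = 1,
                    tasks = "motion_coherence")
  sim <- simulate_behaviour(d, g, seed = 55)
  sim$subjects <- simulate_slopes(sim$subjects, g, seed = 55)
  recs <- simulate_eeg(sim, g, seed = 55)
  got <- purrr::imap_dfr(recs, function(r, id) {
    y <- as.numeric(r$data[1, ])
    des <- build_design(r$events, r$fs, length(y))
    erp <- deconvolve(des, y, lambda = 0)
    dplyr::mutate(extract_slopes(erp), participant_id = id)
  })
  truth <- sim$subjects[match(got$participant_id,
                              sim$subjects$participant_id), ]
  expect_gt(cor(got$eeg_mean, truth$eeg_mean), 0.95)
  expect_lt(max(abs(got$slope_easy - truth$slope_easy)), 0.05)
})
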