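#' Write / read a continuous EEG recording
#'
#' The on-disk form is a flat binary array (float64 little-endian,
#' channels x samples, microvolts) with a JSON sidecar holding the
#' sampling rate, dimensions and the event list.
#'
#' @param rec An `eeg_recording`.
#' @param prefix Path prefix; writes `<prefix>.bin` and `<prefix>.json`.
#' @return `prefix`, invisibly (`read_eeg_recording` returns the
#'   recording).
#' @export
write_eeg_recording <- function(rec, prefix) {
  con <- file(paste0(prefix, ".bin"), "wb")
  writeBin(as.numeric(t(rec$data)), con, size = 8, endian = "little")
  close(con)
  side <- list(sampling_rate_hz = rec$fs,
               n_channels = nrow(rec$data),
               n_samples = ncol(rec$data),
               participant_id = rec$participant_id,
               task = rec$task,
               events = rec$events)
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_eeg_recording
#' @export
read_eeg_recording <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  con <- file(paste0(prefix, ".bin"), "rb")
  x <- readBin(con, "numeric", n = side$n_channels * side$n_samples,
               size = 8, endian = "little")
  close(con)
  structure(list(data = matrix(x, nrow = side$n_channels, byrow = TRUE),
                 fs = side$sampling_rate_hz,
                 events = tibble::as_tibble(side$events),
                 participant_id = side$participant_id,
                 task = side$task),
            class = "eeg_recording")
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> filter -> fit -> evidence table -> EEG
#' deconvolution -> slopes -> joint model from one configuration, writing
#' every artifact plus a manifest (config hash, package version, seed) and
#' a log into a run directory. Rerunning with the same configuration
#' reproduces identical outputs.
#'
#' @param config A named list (or path to a JSON/YAML file) with elements:
#'   `out_dir` (required), `seed` (required), `stages` (subset of
#'   `c("simulate", "filter", "fit", "bf", "eeg", "joint")`), `design`
#'   (arguments to [study_design()]), `generator` (arguments to
#'   [generator_config()]), `sampler` / `joint_sampler` (arguments to
#'   [de_config()]), `eeg` (list: `lambda_grid`, `cv_folds`, `window`),
#'   `blind` (permute group labels with a stored key before fitting).
#' @return Invisibly, a list of the stage results that were produced.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("reading YAML configs requires the yaml package", call. = FALSE)
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  if (is.null(config$out_dir)) stop("config needs `out_dir`", call. = FALSE)
  if (is.null(config$seed)) stop("config needs `seed`", call. = FALSE)
  stages <- config$stages %||%
    c("simulate", "filter", "fit", "bf", "eeg", "joint")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "log.txt")
  say <- function(...) cat(format(Sys.time(), "%H:%M:%S "), ..., "\n",
                           file = logf, append = TRUE)
  cat("", file = logf)
  out <- list()

  design <- do.call(study_design, config$design %||% list())
  gen <- do.call(generator_config, config$generator %||% list())

  need <- function(stage, dep, what) {
    if (is.null(out[[dep]])) {
      stop("stage `", stage, "` needs ", what, "; enable stage `", dep, "`",
           call. = FALSE)
    }
  }

  if ("simulate" %in% stages) {
    say("simulate: behaviour")
    sim <- simulate_behaviour(design, gen, seed = config$seed)
    sim$subjects <- simulate_slopes(sim$subjects, gen, seed = config$seed)
    if (isTRUE(config$blind)) {
      set.seed(config$seed + 999983L)
      ids <- unique(sim$trials$participant_id)
      key <- setNames(sample(sim$subjects$group[match(ids,
                        sim$subjects$participant_id)]), ids)
      sim$trials$group <- unname(key[sim$trials$participant_id])
      jsonlite::write_json(as.list(key),
                           file.path(config$out_dir, "blind_key.json"),
                           auto_unbox = TRUE)
      say("blind: group labels permuted; key stored")
    }
    utils::write.csv(sim$trials, file.path(config$out_dir, "trials.csv"),
                     row.names = FALSE)
    utils::write.csv(sim$subjects,
                     file.path(config$out_dir, "subjects_truth.csv"),
                     row.names = FALSE)
    out$simulate <- sim
  }

  if ("filter" %in% stages) {
    need("filter", "simulate", "a trial table")
    flt <- filter_trials(out$simulate$trials, design$rt_floor)
    utils::write.csv(flt$report,
                     file.path(config$out_dir, "filter_report.csv"),
                     row.names = FALSE)
    out$filter <- flt
    say("filter: ", nrow(flt$trials), " trials retained")
  }

  task1 <- design$tasks[1]

  if ("fit" %in% stages) {
    need("fit", "filter", "filtered trials")
    cfg <- do.call(de_config, c(config$sampler %||% list(),
                                list(seed = config$seed)))
    say("fit: task ", task1)
    tr <- out$filter$trials[out$filter$trials$task == task1, ]
    fit <- fit_hddm(tr, config = cfg, deadline = design$deadline)
    utils::write.csv(tidy(fit),
                     file.path(config$out_dir, "fit_summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(priors = fit$priors, sampler = unclass(cfg),
           s = fit$s, deadline = fit$deadline),
      file.path(config$out_dir, "model_spec.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
    out$fit <- fit
  }

  if ("bf" %in% stages) {
    need("bf", "fit", "a fitted model")
    bf <- bf_table(out$fit)
    utils::write.csv(bf, file.path(config$out_dir, "bf_table.csv"),
                     row.names = FALSE)
    tr <- out$filter$trials[out$filter$trials$task == task1, ]
    dq <- defective_quantiles(tr)
    utils::write.csv(dq$quantiles,
                     file.path(config$out_dir, "defective_quantiles.csv"),
                     row.names = FALSE)
    utils::write.csv(dq$misses,
                     file.path(config$out_dir, "miss_probabilities.csv"),
                     row.names = FALSE)
    out$bf <- bf
    say("bf: ", nrow(bf), " parameters tested")
  }

  if ("eeg" %in% stages) {
    need("eeg", "simulate", "simulated EEG")
    say("eeg: simulate + deconvolve + slopes")
    recs <- simulate_eeg(out$simulate, gen, seed = config$seed,
                         task = task1)
    eegcfg <- config$eeg %||% list()
    grid <- eegcfg$lambda_grid %||% seq(0, 30, by = 0.5)
    folds <- eegcfg$cv_folds %||% 5
    win <- eegcfg$window %||% c(-1, 1)
    fits <- purrr::map(recs, function(r) {
      y <- as.numeric(r$data[1, ])
      des <- build_design(r$events, r$fs, length(y), window = win)
      msk <- mask_artifacts(y, r$fs)
      list(design = des, y = y, mask = msk$mask)
    })
    sel <- select_lambda(fits, grid = grid, k = folds)
    say("eeg: common lambda = ", sel$lambda)
    masks_rle <- purrr::map(fits, function(f) {
      r <- rle(f$mask)
      list(lengths = r$lengths, excluded = r$values,
           fraction = mean(f$mask))
    })
    jsonlite::write_json(masks_rle,
                         file.path(config$out_dir, "artifact_masks.json"),
                         auto_unbox = TRUE)
    slopes <- purrr::imap_dfr(fits, function(f, id) {
      erp <- deconvolve(f$design, f$y, lambda = sel$lambda, mask = f$mask)
      dplyr::mutate(extract_slopes(erp), participant_id = id,
                    .before = 1)
    })
    utils::write.csv(slopes, file.path(config$out_dir, "slopes.csv"),
                     row.names = FALSE)
    out$eeg <- list(slopes = slopes, lambda = sel$lambda)
  }

  if ("joint" %in% stages) {
    need("joint", "filter", "filtered trials")
    need("joint", "eeg", "slope measures")
    cfg <- do.call(de_config,
                   c(config$joint_sampler %||%
                       list(n_iter = 3000, burn_in = 1000,
                            migration_interval = 0),
                     list(seed = config$seed + 1L)))
    tr <- out$filter$trials[out$filter$trials$task == task1, ]
    jf <- fit_joint(tr, out$eeg$slopes, config = cfg,
                    deadline = design$deadline)
    jbf <- bf_table(jf)
    utils::write.csv(jbf, file.path(config$out_dir, "joint_bf_table.csv"),
                     row.names = FALSE)
    utils::write.csv(tidy(jf, pars = "^rho_|^mu_EEG|^delta_EEG",
                          grep = TRUE),
                     file.path(config$out_dir, "joint_rho_summary.csv"),
                     row.names = FALSE)
    out$joint <- jf
    say("joint: done")
  }

  manifest <- list(
    package = "driftslope",
    version = as.character(utils::packageVersion("driftslope")),
    seed = config$seed,
    stages = stages,
    config_hash = digest_config(config),
    r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("manifest written")
  invisible(out)
}

# stable content hash of the run configuration (polynomial rolling hash
# over the serialized payload; avoids an extra dependency)
digest_config <- function(config) {
  raw <- as.integer(serialize(config, NULL, version = 2))
  h <- 0
  for (b in raw) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
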