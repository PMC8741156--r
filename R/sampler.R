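#' Sampler configuration
#'
#' Settings for the blocked differential-evolution MCMC sampler. The
#' defaults match the behavioural analysis: 15 interacting chains, 4000
#' iterations with the first 1500 discarded as burn-in, and chain migration
#' every 14 iterations between iterations 500 and 1100. The joint model
#' conventionally uses `n_iter = 3000`, `burn_in = 1000` and no migration
#' (`migration_interval = 0`).
#'
#' Crossover proposals for a block of dimension d are
#' `current + gamma * (chain_r1 - chain_r2) + eps`, with
#' `gamma = 2.38 / sqrt(2 d)` (scaled by `gamma_scale`), `gamma = 1` with
#' probability `mode_jump_prob` (mode jumping), and
#' `eps ~ U(-jitter, jitter)`.
#'
#' @param n_chains Number of interacting chains (>= 4 for crossover).
#' @param n_iter Total iterations.
#' @param burn_in Iterations discarded in summaries (raw draws retained).
#' @param migration_interval Migrate every this many iterations (0 = never).
#' @param migration_window Iteration range (inclusive) where migration is
#'   active.
#' @param gamma_scale Multiplier on the 2.38/sqrt(2d) step size.
#' @param jitter Half-width of the uniform proposal jitter.
#' @param mode_jump_prob Probability of proposing with gamma = 1.
#' @param seed Integer seed.
#' @return A list of class `de_config`.
#' @export
de_config <- function(n_chains = 15, n_iter = 4000, burn_in = 1500,
                      migration_interval = 14,
                      migration_window = c(500, 1100),
                      gamma_scale = 1, jitter = 0.001,
                      mode_jump_prob = 0.1, seed = 1L) {
  if (burn_in >= n_iter) stop("`burn_in` must be < `n_iter`", call. = FALSE)
  if (migration_interval > 0 &&
      (migration_window[1] < 1 || migration_window[2] > n_iter)) {
    stop("migration window must lie within [1, n_iter]", call. = FALSE)
  }
  structure(list(n_chains = as.integer(n_chains),
                 n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in),
                 migration_interval = as.integer(migration_interval),
                 migration_window = as.integer(migration_window),
                 gamma_scale = gamma_scale, jitter = jitter,
                 mode_jump_prob = mode_jump_prob,
                 seed = as.integer(seed)),
            class = "de_config")
}

# One crossover sweep over a block of coordinates for all chains.
# states: chains x d matrix; lp: current log posteriors; lp_fun(states) ->
# vector of log posteriors for full candidate states. Each chain proposes
# from the current ensemble snapshot with randomly ordered donor pairs
# (which makes the marginal proposal symmetric) and accepts by Metropolis.
de_crossover <- function(states, lp, block, lp_fun, config) {
  nc <- nrow(states)
  if (nc < 4) stop("crossover needs at least 4 chains", call. = FALSE)
  d <- length(block)
  gam <- ifelse(runif(nc) < config$mode_jump_prob, 1,
                config$gamma_scale * 2.38 / sqrt(2 * d))
  r1 <- integer(nc); r2 <- integer(nc)
  for (i in seq_len(nc)) {
    pick <- sample(seq_len(nc)[-i], 2)
    r1[i] <- pick[1]; r2[i] <- pick[2]
  }
  prop <- states
  eps <- matrix(runif(nc * d, -config$jitter, config$jitter), nc, d)
  prop[, block] <- states[, block] +
    gam * (states[r1, block, drop = FALSE] - states[r2, block, drop = FALSE]) +
    eps
  lp_prop <- lp_fun(prop)
  acc <- log(runif(nc)) < (lp_prop - lp)
  acc[is.na(acc)] <- FALSE
  states[acc, block] <- prop[acc, block]
  lp[acc] <- lp_prop[acc]
  list(states = states, lp = lp, accept = acc)
}

# Migration step: a random subset of chains (size ~ U{1..n_chains}) proposes
# a cyclic hand-me-down of states; each receiving chain accepts the incoming
# state by its Metropolis ratio (swaps are proposed, never forced).
de_migrate <- function(states, lp) {
  nc <- nrow(states)
  k <- sample.int(nc, 1)
  set <- sample.int(nc, k)
  donors <- c(set[k], set[-k]) # cyclic: chain set[j] receives from set[j-1]
  snap_states <- states[donors, , drop = FALSE]
  snap_lp <- lp[donors]
  acc <- logical(k)
  for (j in seq_len(k)) {
    if (isTRUE(log(runif(1)) < snap_lp[j] - lp[set[j]])) {
      states[set[j], ] <- snap_states[j, ]
      lp[set[j]] <- snap_lp[j]
      acc[j] <- TRUE
    }
  }
  list(states = states, lp = lp, accept = acc)
}

#' Differential-evolution MCMC on a generic target
#'
#' Samples from an arbitrary log target density with the same crossover /
#' migration machinery used by the hierarchical model fitters. Intended for
#' low-dimensional targets and sampler validation; the model fitters use
#' blocked updates with cached partial targets instead.
#'
#' @param log_target Function mapping a parameter vector to a scalar log
#'   density.
#' @param n_pars Dimension of the target.
#' @param config A [de_config()].
#' @param init Optional chains x n_pars matrix of starting states; defaults
#'   to N(0, 1) draws re-drawn (up to 100 times) until the target is finite.
#' @param blocks Optional list of coordinate index vectors updated as
#'   blocks per iteration (default: one block of all coordinates).
#' @return A `de_samples` object: `draws` (iterations x chains x
#'   parameter), `lp`, acceptance rate, and the config.
#' @export
#' @examples
#' cfg <- de_config(n_chains = 8, n_iter = 500, burn_in = 200,
#'                  migration_interval = 0, seed = 2)
#' fit <- de_sample(function(x) -0.5 * sum(x^2), 2, cfg)
#' colMeans(posterior_matrix(fit))
de_sample <- function(log_target, n_pars, config = de_config(),
                      init = NULL, blocks = NULL) {
  set.seed(config$seed)
  nc <- config$n_chains
  if (is.null(blocks)) blocks <- list(seq_len(n_pars))
  lp_fun <- function(S) apply(S, 1, log_target)
  if (is.null(init)) {
    init <- matrix(rnorm(nc * n_pars), nc, n_pars)
    lp <- lp_fun(init)
    tries <- 0
    while (any(!is.finite(lp)) && tries < 100) {
      bad <- !is.finite(lp)
      init[bad, ] <- matrix(rnorm(sum(bad) * n_pars), sum(bad), n_pars)
      lp[bad] <- lp_fun(init[bad, , drop = FALSE])
      tries <- tries + 1
    }
    if (any(!is.finite(lp))) {
      stop("could not initialise chains at finite log target", call. = FALSE)
    }
  } else {
    lp <- lp_fun(init)
  }
  states <- init
  draws <- array(NA_real_, c(config$n_iter, nc, n_pars))
  n_acc <- 0; n_try <- 0
  for (it in seq_len(config$n_iter)) {
    if (config$migration_interval > 0 &&
        it >= config$migration_window[1] &&
        it <= config$migration_window[2] &&
        it %% config$migration_interval == 0) {
      mg <- de_migrate(states, lp)
      states <- mg$states; lp <- mg$lp
    }
    for (b in blocks) {
      cx <- de_crossover(states, lp, b, lp_fun, config)
      states <- cx$states; lp <- cx$lp
      n_acc <- n_acc + sum(cx$accept); n_try <- n_try + nc
    }
    if (any(is.nan(lp))) {
      stop("log target returned NaN; offending state: ",
           paste(signif(states[which(is.nan(lp))[1], ], 4), collapse = ", "),
           call. = FALSE)
    }
    draws[it, , ] <- states
  }
  structure(list(draws = draws, lp = lp,
                 accept_rate = n_acc / n_try, config = config,
                 par_names = paste0("par", seq_len(n_pars))),
            class = "de_samples")
}

#' Post-burn-in draws as a matrix
#'
#' Flattens a `de_samples` (or fitted model) object's post-burn-in draws to
#' a (draws x parameters) matrix, pooling chains.
#'
#' @param x A `de_samples` object.
#' @param pars Optional parameter name/index subset.
#' @return A numeric matrix.
#' @export
posterior_matrix <- function(x, pars = NULL) {
  keep <- (x$config$burn_in + 1):dim(x$draws)[1]
  d <- x$draws[keep, , , drop = FALSE]
  out <- matrix(aperm(d, c(1, 2, 3)), nrow = length(keep) * dim(d)[2])
  colnames(out) <- x$par_names
  if (!is.null(pars)) out <- out[, pars, drop = FALSE]
  out
}

#' Gelman-Rubin convergence diagnostic
#'
#' Classical potential-scale-reduction statistic computed per parameter
#' from the post-burn-in draws, without chain splitting:
#' `R = sqrt(((n-1)/n W + (1 + 1/m) B/n) / W)` with `W` the mean
#' within-chain variance and `B/n` the between-chain variance of chain
#' means. Identical chains give exactly 1.
#'
#' @param x A `de_samples` / fitted model object, or an iterations x chains
#'   x parameters array.
#' @param burn_in Burn-in to discard when `x` is a bare array (default 0).
#' @return Named numeric vector of R-hat values.
#' @export
gelman_rubin <- function(x, burn_in = 0) {
  if (is.list(x)) {
    draws <- x$draws
    burn_in <- x$config$burn_in
    pn <- x$par_names
  } else {
    draws <- x
    pn <- dimnames(draws)[[3]]
  }
  if (dim(draws)[2] < 2) stop("R-hat needs at least 2 chains", call. = FALSE)
  keep <- (burn_in + 1):dim(draws)[1]
  if (length(keep) < 10) stop("need >= 10 post-burn iterations", call. = FALSE)
  d <- draws[keep, , , drop = FALSE]
  n <- dim(d)[1]; m <- dim(d)[2]; p <- dim(d)[3]
  out <- numeric(p)
  for (k in seq_len(p)) {
    ch <- d[, , k]
    mns <- colMeans(ch)
    W <- mean(apply(ch, 2, var))
    B_n <- var(mns)
    if (W < 1e-300) {
      out[k] <- if (B_n < 1e-300) 1 else Inf
    } else {
      # floored at 1: values below 1 are estimation noise
      out[k] <- max(1, sqrt((n - 1) / n + (1 + 1 / m) * B_n / W))
    }
  }
  names(out) <- if (!is.null(pn)) pn else paste0("par", seq_len(p))
  out
}
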