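#' Goodness-of-fit score
#'
#' Sum of squared scaled distances between model predictions and observed
#' targets: `sum(w * ((pred - obs) / s)^2)`. The per-target scale `s`
#' defaults to `max(|obs|, 10)` so that targets of heterogeneous magnitude
#' (large-country death counts vs small ratios) contribute comparably;
#' passing `scales = 1` gives the unnormalised sum of squared distances.
#' Zero iff predictions match observations exactly; invariant to target
#' ordering; linear in the weights.
#'
#' @param pred,obs aligned numeric vectors (same length).
#' @param weights non-negative weights, recycled.
#' @param scales per-target scales, recycled.
#' @return Non-negative scalar.
#' @export
goodness_of_fit <- function(pred, obs, weights = 1,
                            scales = pmax(abs(obs), 10)) {
  pred <- as.numeric(pred); obs <- as.numeric(obs)
  if (length(pred) != length(obs)) {
    stop("predictions and targets are misaligned", call. = FALSE)
  }
  if (any(!is.finite(pred)) || any(!is.finite(obs))) {
    stop("non-finite predictions or targets", call. = FALSE)
  }
  w <- rep_len(weights, length(obs))
  s <- rep_len(scales, length(obs))
  if (any(w < 0) || any(s <= 0)) stop("invalid weights or scales",
                                      call. = FALSE)
  sum(w * ((pred - obs) / s)^2)
}

#' Tag calibration targets as train or test by year
#'
#' @param targets data.frame with a `year` column.
#' @param cut_year last training year; `year <= cut_year` is train, later
#'   years are test.
#' @return `targets` with a `split` column; idempotent.
#' @export
train_test_split <- function(targets, cut_year) {
  stopifnot(is.data.frame(targets), "year" %in% names(targets))
  targets$split <- ifelse(targets$year <= cut_year, "train", "test")
  if (!any(targets$split == "test")) {
    warning("empty test set: all target years <= cut_year", call. = FALSE)
  }
  targets
}

#' Annealing configuration
#'
#' @param steps number of annealing steps (proposals).
#' @param t0 initial temperature; `NULL` auto-sets it from probe
#'   evaluations so early uphill moves are accepted with probability about
#'   0.8; `0` gives pure greedy descent.
#' @param cooling geometric cooling factor in (0, 1); default shrinks the
#'   temperature by 1000x over the run.
#' @param proposal_scale per-parameter proposal standard deviation on the
#'   transformed scale (recycled).
#' @param restart_prob probability a proposal is a fresh prior draw.
#' @param subset_prob probability each parameter is perturbed in a
#'   non-restart proposal (at least one always is).
#' @param seed RNG seed for the annealing chain.
#' @param crn_seed common-random-numbers seed passed to every simulator
#'   evaluation so goodness-of-fit comparisons share first-order noise;
#'   defaults to a fixed function of `seed`.
#' @param n_probe prior draws used to auto-set `t0`.
#' @return List of class `anneal_config`.
#' @export
anneal_config <- function(steps, t0 = NULL, cooling = NULL,
                          proposal_scale = 0.1, restart_prob = 0.1,
                          subset_prob = 0.4, seed = 1L, crn_seed = NULL,
                          n_probe = 8L) {
  stopifnot(.is_count(steps), steps >= 1)
  if (is.null(cooling)) cooling <- 1e-3^(1 / steps)
  stopifnot(cooling > 0, cooling < 1, restart_prob >= 0, restart_prob <= 1,
            subset_prob > 0, subset_prob <= 1)
  if (!is.null(t0)) stopifnot(t0 >= 0)
  structure(list(steps = as.integer(steps), t0 = t0, cooling = cooling,
                 proposal_scale = proposal_scale,
                 restart_prob = restart_prob, subset_prob = subset_prob,
                 seed = as.integer(seed), crn_seed = crn_seed,
                 n_probe = as.integer(n_probe)),
            class = "anneal_config")
}

#' Calibrate parameters by simulated annealing
#'
#' Metropolis-style stochastic optimisation of a simulator against targets:
#' proposals perturb a random subset of parameters on the transformed scale
#' (with occasional fresh prior draws for restarts), worse scores are
#' accepted with probability `exp(-delta / T)` and the temperature follows
#' a geometric cooling schedule. Every evaluated parameter set is archived
#' with its score, so the archive doubles as the calibration posterior from
#' which the best sets are resampled.
#'
#' @param prior_sampler function() returning a named numeric parameter
#'   vector on the transformed scale.
#' @param simulator function(theta, seed) returning predictions aligned
#'   with `targets` (one per row); errors are recorded and the proposal
#'   rejected.
#' @param targets data.frame with columns `value` and optionally `weight`,
#'   or a plain numeric vector of observations.
#' @param config an [anneal_config()].
#' @param scales per-target goodness-of-fit scales (see
#'   [goodness_of_fit()]); the default normalises by `max(|obs|, 10)`,
#'   while `scales = 1` is the plain sum of squared distances, appropriate
#'   when all targets share one magnitude (e.g. small death counts).
#' @return Object of class `posterior_archive`: list with `params` (matrix,
#'   one evaluated set per row, sorted by score), `scores`, `best_trace`
#'   (running best score), `accepted` (logical per step), `temps` and
#'   `n_failed`.
#' @export
anneal <- function(prior_sampler, simulator, targets, config,
                   scales = NULL) {
  stopifnot(inherits(config, "anneal_config"))
  obs <- if (is.data.frame(targets)) targets$value else as.numeric(targets)
  if (length(obs) == 0L) stop("targets must be nonempty", call. = FALSE)
  wts <- if (is.data.frame(targets) && !is.null(targets$weight)) {
    targets$weight
  } else rep(1, length(obs))
  if (is.null(scales)) scales <- pmax(abs(obs), 10)
  set.seed(config$seed)
  crn <- if (is.null(config$crn_seed)) config$seed + 7919L else config$crn_seed
  n_failed <- 0L
  evalf <- function(th) {
    pred <- tryCatch(simulator(th, crn), error = function(e) NULL)
    if (is.null(pred) || length(pred) != length(obs) ||
        any(!is.finite(pred))) {
      n_failed <<- n_failed + 1L
      return(NA_real_)
    }
    goodness_of_fit(pred, obs, wts, scales)
  }

  th <- prior_sampler()
  p <- length(th)
  psd <- rep_len(config$proposal_scale, p)
  sc <- evalf(th)
  params <- matrix(NA_real_, config$steps + config$n_probe + 1L, p,
                   dimnames = list(NULL, names(th)))
  scores <- rep(NA_real_, nrow(params))
  params[1L, ] <- th; scores[1L] <- sc

  # probe the prior to set the starting temperature
  probe_sc <- sc
  for (i in seq_len(config$n_probe)) {
    thp <- prior_sampler()
    scp <- evalf(thp)
    params[1L + i, ] <- thp; scores[1L + i] <- scp
    probe_sc <- c(probe_sc, scp)
    if (!is.na(scp) && (is.na(sc) || scp < sc)) { th <- thp; sc <- scp }
  }
  t0 <- config$t0
  if (is.null(t0)) {
    d <- abs(diff(probe_sc[is.finite(probe_sc)]))
    t0 <- if (length(d) && mean(d) > 0) mean(d) / -log(0.8) else 1
  }
  if (is.na(sc)) stop("no successful simulator evaluation in probes",
                      call. = FALSE)

  accepted <- logical(config$steps)
  temps <- t0 * config$cooling^seq_len(config$steps)
  best_trace <- numeric(config$steps)
  chain_trace <- numeric(config$steps)
  best <- sc
  off <- config$n_probe + 1L
  for (k in seq_len(config$steps)) {
    if (stats::runif(1) < config$restart_prob) {
      th2 <- prior_sampler()
    } else {
      sel <- stats::runif(p) < config$subset_prob
      if (!any(sel)) sel[sample.int(p, 1L)] <- TRUE
      th2 <- th
      th2[sel] <- th2[sel] + stats::rnorm(sum(sel), 0, psd[sel])
    }
    sc2 <- evalf(th2)
    params[off + k, ] <- th2; scores[off + k] <- sc2
    if (!is.na(sc2)) {
      dlt <- sc2 - sc
      acc <- dlt <= 0 ||
        (temps[k] > 0 && stats::runif(1) < exp(-dlt / temps[k]))
      if (acc) { th <- th2; sc <- sc2; accepted[k] <- TRUE }
      if (sc2 < best) best <- sc2
    }
    best_trace[k] <- best
    chain_trace[k] <- sc
  }

  ok <- !is.na(scores)
  params <- params[ok, , drop = FALSE]
  scores <- scores[ok]
  o <- order(scores)
  structure(list(params = params[o, , drop = FALSE], scores = scores[o],
                 best_trace = best_trace, chain_trace = chain_trace,
                 accepted = accepted, temps = temps, t0 = t0,
                 n_failed = n_failed),
            class = "posterior_archive")
}

#' Sample parameter sets from a posterior archive
#'
#' Keeps the `k` best-fitting unique parameter sets and draws `n` of them
#' uniformly with replacement; each draw carries a fresh first-order seed,
#' so simulating the draws propagates both parameter (second-order) and
#' stochastic (first-order) uncertainty. Ties at the k-th score are broken
#' deterministically by the parameter set's printed representation.
#'
#' @param archive a `posterior_archive` from [anneal()].
#' @param k number of best sets to keep (default 100).
#' @param n number of simulation iterations to draw (default 1000).
#' @param seed RNG seed.
#' @return List with `params` (n x p matrix of drawn sets), `index`
#'   (which of the k best each draw uses), `seeds` (first-order seed per
#'   draw) and `kept` (the k best unique sets).
#' @export
posterior_sample <- function(archive, k = 100L, n = 1000L, seed = 1L) {
  stopifnot(inherits(archive, "posterior_archive"), .is_count(k),
            .is_count(n), k >= 1, n >= 1)
  key <- apply(archive$params, 1L, function(r) {
    paste(format(r, digits = 15), collapse = ",")
  })
  dup <- duplicated(key)
  params <- archive$params[!dup, , drop = FALSE]
  scores <- archive$scores[!dup]
  key <- key[!dup]
  if (nrow(params) < k) {
    stop("archive holds fewer than k unique parameter sets", call. = FALSE)
  }
  o <- order(scores, key)
  kept <- params[o[seq_len(k)], , drop = FALSE]
  set.seed(seed)
  idx <- sample.int(k, n, replace = TRUE)
  list(params = kept[idx, , drop = FALSE], index = idx,
       seeds = seed + seq_len(n), kept = kept)
}

#' Posterior predictive check
#'
#' Compares prediction intervals with observed targets: the coverage
#' probability (percentage of targets whose observed value lies inside the
#' 95% uncertainty interval), the mean absolute error and the mean error of
#' the predictive means, reported overall and per group/split when given.
#'
#' @param mean,ui_lo,ui_hi per-target predictive mean and interval bounds.
#' @param obs observed target values, aligned with the predictions.
#' @param group,split optional per-target labels to stratify the report.
#' @return data.frame of class `ppc_report` with columns group, split, n,
#'   coverage (percent), mae, me.
#' @export
ppc <- function(mean, ui_lo, ui_hi, obs, group = NULL, split = NULL) {
  n <- length(obs)
  if (length(mean) != n || length(ui_lo) != n || length(ui_hi) != n) {
    stop("predictions and targets are misaligned", call. = FALSE)
  }
  if (n == 0L) stop("no targets", call. = FALSE)
  if (any(!is.finite(mean)) || any(!is.finite(obs)) ||
      any(!is.finite(ui_lo)) || any(!is.finite(ui_hi))) {
    stop("unmatched or non-finite entries in the PPC input", call. = FALSE)
  }
  g <- if (is.null(group)) rep("all", n) else as.character(group)
  s <- if (is.null(split)) rep("all", n) else as.character(split)
  keyed <- split(seq_len(n), paste(g, s, sep = "\r"))
  rows <- lapply(names(keyed), function(kk) {
    i <- keyed[[kk]]
    parts <- strsplit(kk, "\r", fixed = TRUE)[[1L]]
    data.frame(group = parts[1L], split = parts[2L], n = length(i),
               coverage = 100 * base::mean(obs[i] >= ui_lo[i] &
                                             obs[i] <= ui_hi[i]),
               mae = base::mean(abs(mean[i] - obs[i])),
               me = base::mean(mean[i] - obs[i]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ppc_report", "data.frame")
  out
}
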