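# Calibration bridge: exposes a named subset of parameter-set entries as a
# flat transformed-scale vector (theta) that the annealer can perturb, and
# wraps the engine as a simulator aligned with a target table.

#' Default free parameters for world calibration
#'
#' The calibration exercise frees the quantities that reported-death
#' targets are most informative about: per-country case-fatality shifts
#' (logit scale), per-country CRVS capture baselines (logit), log
#' multipliers on hemorrhage/sepsis incidence and the late-death hazard,
#' a shift on the met-need trend slope, a shift on the abortion baseline
#' and a logit shift on the indirect-death proportion. With three or more
#' countries this yields 10+ free parameters.
#'
#' @param world a world object.
#' @return data.frame with columns name, prior_mean, prior_sd describing
#'   independent normal priors on the transformed scale.
#' @export
free_parameters <- function(world) {
  ctys <- world$countries
  # prior dispersions equal the generating hierarchy's total path sd, so
  # the annealer samples from the same prior the world was drawn from
  cat_ <- default_priors()
  sd_path <- function(p) sqrt(sum(p$level_sds^2))
  rbind(
    data.frame(name = paste0("cfr_shift.", ctys), prior_mean = 0,
               prior_sd = sd_path(cat_$cfr_shift)),
    data.frame(name = paste0("capture_b.", ctys),
               prior_mean = stats::qlogis(0.55),
               prior_sd = sd_path(cat_$capture_b)),
    data.frame(name = "log_pph_mult", prior_mean = 0, prior_sd = 0.3),
    data.frame(name = "log_sepsis_mult", prior_mean = 0, prior_sd = 0.3),
    data.frame(name = "log_late_mult", prior_mean = 0, prior_sd = 0.4),
    data.frame(name = "metneed_slope_shift", prior_mean = 0,
               prior_sd = 0.02),
    data.frame(name = "abortion_b_shift", prior_mean = 0, prior_sd = 0.4),
    data.frame(name = "p_indirect_shift", prior_mean = 0, prior_sd = 0.4)
  )
}

#' Apply a free-parameter vector to a parameter set
#'
#' @param pset base `parameter_set`.
#' @param theta named numeric vector over [free_parameters()] names.
#' @param world the world (for country order).
#' @return Modified `parameter_set`.
#' @export
apply_free_parameters <- function(pset, theta, world) {
  ctys <- world$countries
  C <- length(ctys)
  cfr <- theta[paste0("cfr_shift.", ctys)]
  if (!anyNA(cfr)) pset$comp$cfr_shift <- unname(cfr)
  cap <- theta[paste0("capture_b.", ctys)]
  if (!anyNA(cap)) pset$hs$capture_b <- unname(cap)
  if ("log_pph_mult" %in% names(theta)) {
    pset$comp$base[, 3L] <- pmin(1, pset$comp$base[, 3L] *
                                   exp(theta[["log_pph_mult"]]))
  }
  if ("log_sepsis_mult" %in% names(theta)) {
    pset$comp$base[, 4L] <- pmin(1, pset$comp$base[, 4L] *
                                   exp(theta[["log_sepsis_mult"]]))
  }
  if ("log_late_mult" %in% names(theta)) {
    pset$comp$late_hazard <- pmin(0.05, rep_len(pset$comp$late_hazard, C) *
                                    exp(theta[["log_late_mult"]]))
  }
  if ("metneed_slope_shift" %in% names(theta)) {
    pset$fp$metneed_slope <- rep_len(pset$fp$metneed_slope, C) +
      theta[["metneed_slope_shift"]]
  }
  if ("abortion_b_shift" %in% names(theta)) {
    pset$fp$abortion_b <- rep_len(pset$fp$abortion_b, C) +
      theta[["abortion_b_shift"]]
  }
  if ("p_indirect_shift" %in% names(theta)) {
    pset$demog$p_indirect <- stats::plogis(
      stats::qlogis(rep_len(pset$demog$p_indirect, C)) +
        theta[["p_indirect_shift"]])
  }
  pset
}

#' Ground-truth value of the free-parameter vector
#'
#' For parameters exposed directly (case-fatality shifts, capture
#' baselines) this is the truth's value; for multiplier/shift parameters
#' the truth corresponds to zero (no deviation from the generating set).
#'
#' @param truth the generating `parameter_set`.
#' @param world the world.
#' @return Named numeric vector aligned with [free_parameters()].
#' @export
true_theta <- function(truth, world) {
  ctys <- world$countries
  C <- length(ctys)
  th <- c(stats::setNames(rep_len(truth$comp$cfr_shift, C),
                          paste0("cfr_shift.", ctys)),
          stats::setNames(rep_len(truth$hs$capture_b, C),
                          paste0("capture_b.", ctys)),
          log_pph_mult = 0, log_sepsis_mult = 0, log_late_mult = 0,
          metneed_slope_shift = 0, abortion_b_shift = 0,
          p_indirect_shift = 0)
  th[free_parameters(world)$name]
}

#' Prior sampler over the free parameters
#'
#' @param free a [free_parameters()] table.
#' @return function() drawing one named theta vector.
#' @export
make_prior_sampler <- function(free) {
  function() {
    stats::setNames(stats::rnorm(nrow(free), free$prior_mean, free$prior_sd),
                    free$name)
  }
}

#' Engine-backed simulator aligned with a target table
#'
#' Returns `function(theta, seed)` that applies `theta` to the base
#' parameter set, runs the engine and reads off the predicted reported
#' deaths for each target row (country, year, cause, source; cause
#' `"total"` sums the eight groups).
#'
#' @param world,pset_base world and base `parameter_set`.
#' @param targets target table as from [generate_synthetic_targets()].
#' @return Simulator closure for [anneal()].
#' @export
make_simulator <- function(world, pset_base, targets) {
  ci <- match(targets$country, world$countries)
  si <- match(targets$source, .report_sources)
  if (anyNA(ci) || anyNA(si)) stop("targets reference unknown countries or sources",
                                   call. = FALSE)
  function(theta, seed) {
    pset <- apply_free_parameters(pset_base, theta, world)
    tl <- simulate_world(world, pset, seed = seed)
    yi <- match(targets$year, tl$years)
    tot <- apply(tl$reported, c(1, 2, 4), sum)
    vapply(seq_len(nrow(targets)), function(i) {
      if (targets$cause[i] == "total") tot[ci[i], yi[i], si[i]]
      else tl$reported[ci[i], yi[i], match(targets$cause[i], maternal_causes),
                       si[i]]
    }, numeric(1))
  }
}

#' End-to-end posterior predictive check on a world
#'
#' Simulates `n` posterior draws (parameter sets resampled from the
#' archive's best `k`, each with its own first-order seed), forms per-target
#' predictive means and 95% uncertainty intervals, and reports coverage,
#' MAE and ME by target split.
#'
#' @param world,pset_base world and base parameter set.
#' @param archive a `posterior_archive`.
#' @param targets target table with `split` labels.
#' @param k,n archive size and iteration count for [posterior_sample()].
#' @param seed RNG seed.
#' @param noise_sd observation-noise standard deviation of the target
#'   generator; predictive replicates add the same truncated Gaussian
#'   noise as [generate_synthetic_targets()], so intervals are proper
#'   posterior predictive intervals for the observed targets.
#' @return List with `report` (a `ppc_report`), `pred` (n x targets matrix
#'   of predictive replicates) and `draws` (the posterior sample).
#' @export
ppc_world <- function(world, pset_base, archive, targets, k = 100L,
                      n = 200L, seed = 1L, noise_sd = 0) {
  draws <- posterior_sample(archive, k = k, n = n, seed = seed)
  sim <- make_simulator(world, pset_base, targets)
  pred <- matrix(NA_real_, n, nrow(targets))
  for (i in seq_len(n)) {
    pred[i, ] <- sim(draws$params[i, ], draws$seeds[i])
  }
  if (noise_sd > 0) {
    set.seed(seed + 999L)
    pred[] <- pmax(0, pred + stats::rnorm(length(pred), 0, noise_sd))
  }
  mu <- colMeans(pred)
  qs <- apply(pred, 2L, stats::quantile, probs = c(0.025, 0.975), type = 7)
  report <- ppc(mu, qs[1L, ], qs[2L, ], targets$value,
                group = targets$cause, split = targets$split)
  overall <- ppc(mu, qs[1L, ], qs[2L, ], targets$value,
                 split = targets$split)
  list(report = rbind(report, overall), pred = pred, draws = draws)
}
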