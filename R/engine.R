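# Monthly-cycle open-population engine.
#
# The population is a set of parallel vectors held in an environment; every
# event is applied to index subsets in a fixed canonical order each cycle:
#   (1) person-time + background (non-obstetric) mortality
#   (2) aging
#   (3) family-planning update
#   (4) conception attempt
#   (5) pregnancy-month update (losses, abortion decision, delivery + care
#       pathway)
#   (6) postpartum update (late maternal hazard)
#   (7) new entrants (each January)
# Randomness comes from one seeded stream; because women are always
# processed in fixed vectorised order, runs are bit-reproducible.

.pop_fields <- c("id", "ci", "sg", "age", "w", "alive", "debut", "menop", "desired",
                 "living", "since_birth", "meth", "mon", "dur", "pend",
                 "infert", "preg", "gest", "nfet", "nfem", "sched",
                 "intended", "ect", "anc", "rboost", "abdec", "pp", "bfr",
                 "bfe", "hb", "nmisc", "nect", "nsb", "npee", "ncs", "nab",
                 "intent")  # alive: marked dead mid-cycle, compacted once per cycle

.bern <- function(n, p) stats::runif(n) < p

# accumulate weights into arr at (possibly duplicated) linear indices
.add_at <- function(arr, lin, wt) {
  if (length(lin) == 0L) return(arr)
  w0 <- wt[1L]
  if (all(wt == w0)) { # uniform weights: tabulate is much faster
    arr + tabulate(lin, nbins = length(arr)) * w0
  } else {
    s <- rowsum(wt, lin)
    ii <- as.integer(rownames(s))
    arr[ii] <- arr[ii] + s[, 1L]
    arr
  }
}

.lin2 <- function(i, j, d1) i + (j - 1L) * d1
.lin3 <- function(i, j, k, d1, d2) i + (j - 1L) * d1 + (k - 1L) * d1 * d2

#' Draw age at menopause
#'
#' Normal on the month scale, truncated to 40--60 years to avoid
#' pathological draws.
#' @param n number of draws.
#' @param mean_m,sd_m mean and standard deviation in months (`sd_m >= 0`).
#' @return Integer months.
#' @export
draw_menopause <- function(n, mean_m, sd_m) {
  if (any(sd_m < 0)) stop("sd_m must be >= 0", call. = FALSE)
  if (all(sd_m == 0)) return(rep(as.integer(round(mean_m)), n))
  lo <- stats::pnorm(480, mean_m, sd_m)
  hi <- stats::pnorm(720, mean_m, sd_m)
  as.integer(round(stats::qnorm(lo + stats::runif(n) * (hi - lo),
                                mean_m, sd_m)))
}

#' Anemia status from hemoglobin
#'
#' WHO thresholds: anemic below 11 g/dL when pregnant, below 12 g/dL
#' otherwise.
#' @param hb hemoglobin (g/dL).
#' @param pregnant logical, vectorised.
#' @return Logical.
#' @export
is_anemic <- function(hb, pregnant = FALSE) {
  hb < 12 - as.numeric(pregnant) # thresholds 11 (pregnant) / 12 g/dL
}

#' Classify a non-obstetric death
#'
#' With probability `p_injury` the death is injury-related (never maternal,
#' but pregnancy-related if it occurs in the risk window). Otherwise, a
#' death during pregnancy or the 42-day window is an indirect maternal
#' death with probability `p_indirect`; all remaining deaths are other
#' non-maternal deaths.
#'
#' @param in_window logical: pregnant or within the 42-day window.
#' @param p_injury,p_indirect probabilities, recycled.
#' @return Character vector: `"injury"`, `"indirect"` or
#'   `"other_nonmaternal"`.
#' @export
classify_nonobstetric_death <- function(in_window, p_injury, p_indirect) {
  n <- length(in_window)
  inj <- .bern(n, rep_len(p_injury, n))
  ind <- !inj & in_window & .bern(n, rep_len(p_indirect, n))
  ifelse(inj, "injury", ifelse(ind, "indirect", "other_nonmaternal"))
}

#' Monthly conception probability
#'
#' Women using no method conceive at their age-specific fecundity times the
#' lactational-amenorrhea multiplier; method users conceive at the method's
#' monthly failure probability (independent of fecundity).
#'
#' @param fecundity monthly fecundity (no-method).
#' @param lam_mult lactational amenorrhea multiplier (1 when not nursing or
#'   beyond 9 months postpartum).
#' @param using_method logical.
#' @param failure_monthly monthly method failure probability.
#' @return Probability vector.
#' @export
conception_prob <- function(fecundity, lam_mult, using_method,
                            failure_monthly) {
  p <- fecundity * lam_mult
  fm <- rep_len(failure_monthly, length(p))
  p[using_method] <- fm[using_method]
  p
}

# ---------------------------------------------------------------------------
# parameter resolution: parameter_set -> flat year-expanded arrays

#' Resolve a parameter set into engine arrays
#'
#' Expands trend specifications over the simulated years and pre-computes
#' every per-country/site/year array the monthly loop needs (monthly
#' mortality, site-choice distributions, intervention effectiveness,
#' reporting capture probabilities, ...). Interpretable but slow structures
#' (trend baselines + slopes) live in the `parameter_set`; this function is
#' the single bridge to the fast representation.
#'
#' @param world a world from [generate_synthetic_world()].
#' @param pset a `parameter_set` (the world's truth, or a calibrated
#'   variant).
#' @param years years to simulate (default the world's years).
#' @return Environment of engine arrays.
#' @export
build_engine_params <- function(world, pset, years = world$years) {
  stopifnot(inherits(pset, "parameter_set"))
  C <- length(world$countries)
  Y <- length(years)
  t <- seq_len(Y) - 1
  yi_w <- match(years, world$years)
  if (anyNA(yi_w)) stop("years outside the world's lifetable range",
                        call. = FALSE)
  P <- new.env(parent = emptyenv())
  P$C <- C; P$Y <- Y; P$years <- as.integer(years)
  P$ctys <- world$countries
  P$ppa <- world$persons_per_agent
  P$entry <- world$entry_schedule[, yi_w, drop = FALSE]
  P$shares <- world$subgroup_shares

  P$qm <- 1 - (1 - world$lifetable[, , yi_w, drop = FALSE])^(1 / 12)
  P$p_injury <- world$p_injury
  P$p_indirect <- rep_len(pset$demog$p_indirect, C)

  b <- pset$bio
  P$fec <- matrix(b$fec_band, C, 8L)
  P$twin <- b$twin_mono + b$twin_di
  P$pF <- 1 / (1 + b$sr_primary)
  P$sr1 <- b$sr_primary
  P$sr2 <- rep_len(b$sr_secondary, C)
  P$misc <- rep_len(b$misc_base, C); P$misc_rr <- b$misc_rr_hist
  P$ect <- rep_len(b$ect_base, C); P$ect_rr <- b$ect_rr_recur
  P$sbf <- rep_len(b$sb_base, C); P$sbm <- pmin(1, P$sbf * b$sb_rr_male)
  P$ddist <- b$delivery_dist
  P$lam_ex <- b$lam_excl_mult; P$lam_pa <- b$lam_part_mult
  P$menop_mean <- b$menop_mean_m; P$menop_sd <- b$menop_sd_m
  P$hb_mean <- matrix(b$hb_mean, C, 6L); P$hb_sd <- b$hb_sd
  P$bf_prob <- rep_len(b$bf_prob, C)
  P$bf_excl <- rep_len(b$bf_excl_prob, C)
  P$bf_mean <- b$bf_mean_months

  f <- pset$fp
  P$debut_med <- matrix(f$debut_median_m, C, 6L)
  P$debut_sd <- f$debut_logsd
  P$dfs_w <- rep_len(f$dfs_w, C); P$dfs_k <- f$dfs_kstar
  P$dfs_l <- rep_len(f$dfs_lambda, C)
  P$space_m <- f$spacing_months
  tv <- function(bvec, svec, alpha, scale = "logit") {
    # always a C x Y matrix, also for single-country worlds
    matrix(trend_value(trend_spec(rep_len(bvec, C), rep_len(svec, C),
                                  alpha, scale), t), C, Y)
  }
  P$metneed <- tv(f$metneed_b, f$metneed_slope, f$metneed_alpha)
  P$mix <- rbind(spacing = f$mix_spacing, limiting = f$mix_limiting)
  mc <- t(apply(P$mix, 1L, cumsum))
  P$mixcum <- mc / mc[, 4L]
  P$failm <- annual_to_monthly(f$fail_annual)
  P$durm <- f$dur_mean
  P$switch <- f$switch_prob
  P$abort <- tv(f$abortion_b, f$abortion_slope, f$abortion_alpha)
  P$absafe <- tv(f$abortion_safe_b, f$abortion_safe_slope, 1)
  P$ucfr <- f$unsafe_cfr; P$urr_an <- f$unsafe_rr_anemia
  P$infert <- f$infert_prob

  h <- pset$hs
  P$anc_any <- tv(h$anc_any_b, h$anc_any_slope, 1)
  P$anc_l <- rep_len(h$anc_lambda, C)
  P$anc_hb <- h$anc_hb_coef; P$anc_rb <- h$anc_recog_coef

  # site distribution: softmax over site logits + subgroup facility shift +
  # facility trend; cumulative over sites for fast categorical draws
  sbl <- matrix(h$site_base_logit, C, 5L)
  sitecum <- array(0, c(C, 6L, Y, 5L))
  fac <- c(0, 0, 1, 1, 1) # facility indicator
  for (ci in seq_len(C)) for (g in 1:6) for (yy in seq_len(Y)) {
    lg <- sbl[ci, ] + fac * (h$sg_facility_shift[g] +
                               h$site_trend_slope[ci] * t[yy])
    p <- exp(lg - max(lg)); p <- p / sum(p)
    sitecum[ci, g, yy, ] <- cumsum(p)
  }
  P$sitecum <- sitecum
  P$ecs <- tv(h$ecs_b, h$ecs_slope, 1)
  P$recog <- h$recog_base; P$recog_sev <- h$recog_sev_boost
  P$transport <- h$transport; P$refc <- h$ref_p_cemoc
  qual <- array(0, c(C, 5L, Y))
  qb <- matrix(h$quality_base, C, 5L)
  for (yy in seq_len(Y)) {
    qual[, , yy] <- stats::plogis(stats::qlogis(.clip(qb, 1e-6, 1 - 1e-6)) +
                                    h$quality_slope * t[yy])
  }
  P$qual <- qual
  cap <- array(0, c(C, 5L, Y, 2L))
  for (yy in seq_len(Y)) {
    lg <- outer(rep_len(h$capture_b, C) + h$capture_slope * t[yy],
                h$capture_site_shift, `+`)
    cap[, , yy, 1L] <- stats::plogis(lg)
    cap[, , yy, 2L] <- stats::plogis(lg + h$survey_boost)
  }
  P$capture <- cap

  cm <- pset$comp
  P$cbase <- matrix(cm$base, C, 5L)
  P$rr <- cm[c("rr_pee_young", "rr_pee_old", "rr_pee_anemia", "rr_pee_mult",
               "rr_pee_hist", "rr_ol_young", "rr_pph_anemia", "rr_sep_anemia",
               "rr_sep_cs")]
  P$sevf <- cm$sev_frac
  cfr <- array(0, c(C, 5L, 2L, 5L)) # country x type x severity x site
  shift <- rep_len(cm$cfr_shift, C)
  for (tt in 1:5) for (s in 1:5) {
    base <- cm$cfr_severe[tt, s]
    nonsev <- if (tt == 5L) base else base * cm$cfr_nonsev_frac
    cfr[, tt, 2L, s] <- stats::plogis(stats::qlogis(base) + shift)
    cfr[, tt, 1L, s] <- stats::plogis(stats::qlogis(nonsev) + shift)
  }
  P$cfr <- cfr
  P$ectcfr <- stats::plogis(outer(shift, stats::qlogis(cm$ect_cfr), `+`))
  P$ipsb <- cm$ip_sb_prob
  P$late <- rep_len(cm$late_hazard, C)

  # interventions -> effectiveness arrays
  avail <- function(iv) {
    a <- matrix(0, 5L, Y)
    ok <- seq_len(5L) >= iv$min_site
    for (yy in seq_len(Y)) {
      a[ok, yy] <- stats::plogis(stats::qlogis(iv$avail_base[ok]) +
                                   iv$avail_slope * t[yy])
    }
    a
  }
  eff_arr <- function(iv) { # 1 - a*kappa*(1-RR), by country x site x year
    a <- avail(iv)
    out <- array(1, c(C, 5L, Y))
    for (yy in seq_len(Y)) {
      qy <- matrix(qual[, , yy], C, 5L)
      out[, , yy] <- 1 - sweep(qy, 2L, a[, yy], `*`) * (1 - iv$efficacy)
    }
    out
  }
  iv <- pset$interv
  P$prev_pph <- eff_arr(iv$amtsl)
  P$prev_sep <- eff_arr(iv$clean_delivery)
  pg <- avail(iv$partograph)
  olb <- array(0, c(C, 5L, Y))
  for (yy in seq_len(Y)) {
    olb[, , yy] <- sweep(matrix(qual[, , yy], C, 5L), 2L, pg[, yy],
                         `*`) * iv$partograph$boost_logit
  }
  P$ol_recboost <- olb
  cure <- array(1, c(C, 5L, 5L, Y)) # country x type x site x year
  cure[, 1L, , ] <- eff_arr(iv$hypertension_mgmt)
  cure[, 2L, , ] <- eff_arr(iv$assisted_delivery)
  cure[, 3L, , ] <- eff_arr(iv$hemorrhage_mgmt)
  cure[, 4L, , ] <- eff_arr(iv$antibiotics)
  P$cure <- cure
  P$ect_cure <- eff_arr(iv$ectopic_mgmt)
  P
}

# ---------------------------------------------------------------------------
# population initialisation

.init_women <- function(P, ci, age_m) {
  n <- length(ci)
  u <- stats::runif(n)
  sg <- integer(n)
  for (cc in unique(ci)) {
    k <- which(ci == cc)
    cs <- cumsum(P$shares[cc, ])
    sg[k] <- 1L + findInterval(u[k], cs[-6L])
  }
  debut <- as.integer(round(stats::rlnorm(
    n, log(P$debut_med[.lin2(ci, sg, P$C)]), P$debut_sd)))
  agey <- age_m %/% 12L
  active_yrs <- pmax(0, agey - debut %/% 12L)
  lam0 <- pmax(0, pmin(agey, 40L) - 18L) * 0.16 * (P$dfs_l[ci] / 3.2)
  living <- as.integer(pmin(stats::rpois(n, lam0 * (active_yrs > 0)), 9L))
  since <- ifelse(living > 0L,
                  as.integer(stats::runif(n, 0, 72)), 9999L)
  list(
    id = integer(n), ci = ci, sg = sg, age = as.integer(age_m),
    w = rep(1, n), alive = rep(TRUE, n),
    debut = debut,
    menop = draw_menopause(n, P$menop_mean, P$menop_sd),
    desired = .dfs_percountry(n, ci, P),
    living = living, since_birth = since,
    meth = integer(n), mon = integer(n), dur = rep(Inf, n),
    pend = rep(TRUE, n), infert = rep(FALSE, n),
    preg = rep(FALSE, n), gest = integer(n), nfet = integer(n),
    nfem = integer(n), sched = integer(n), intended = rep(FALSE, n),
    ect = rep(FALSE, n), anc = integer(n), rboost = numeric(n),
    abdec = rep(FALSE, n), pp = rep(-1L, n), bfr = integer(n),
    bfe = rep(FALSE, n),
    hb = stats::rnorm(n, P$hb_mean[.lin2(ci, sg, P$C)], P$hb_sd),
    nmisc = integer(n), nect = integer(n), nsb = integer(n),
    npee = integer(n), ncs = integer(n), nab = integer(n),
    intent = rep(2L, n)
  )
}

.dfs_percountry <- function(n, ci, P) {
  k <- stats::rpois(n, P$dfs_l[ci])
  infl <- stats::runif(n) < P$dfs_w[ci]
  k[infl] <- P$dfs_k
  as.integer(k)
}

#' Initialise the simulated population
#'
#' Draws the starting cross-section for every country: ages uniform over
#' 10--54 years, subgroup membership from the world's subgroup shares,
#' sexual debut (log-normal), menopause age, hemoglobin, desired family
#' size (inflated Poisson) and an age-consistent number of living children.
#' The burn-in years let the cross-section forget this synthetic
#' initialisation before reporting starts.
#'
#' @param world a world object.
#' @param P engine arrays from [build_engine_params()].
#' @param n_agents women per country.
#' @return Population environment.
#' @export
init_population <- function(world, P, n_agents = world$n_agents) {
  C <- P$C
  ci <- rep(seq_len(C), each = n_agents)
  age <- as.integer(stats::runif(length(ci), 120, 659))
  pop <- list2env(.init_women(P, ci, age), parent = emptyenv())
  pop$id <- seq_along(pop$ci)
  pop$next_id <- length(pop$ci) + 1L
  pop
}

.append_women <- function(pop, new) {
  n <- length(new$ci)
  if (n == 0L) return(invisible(pop))
  new$id <- seq.int(pop$next_id, length.out = n)
  pop$next_id <- pop$next_id + n
  for (f in .pop_fields) pop[[f]] <- c(pop[[f]], new[[f]])
  invisible(pop)
}

.remove_women <- function(pop, dead_idx) {
  if (length(dead_idx) == 0L) return(invisible(pop))
  for (f in .pop_fields) pop[[f]] <- pop[[f]][-dead_idx]
  invisible(pop)
}

# ---------------------------------------------------------------------------
# death recording

# cause_idx: index into maternal_causes, NA for non-maternal
.record_deaths <- function(tl, P, yi, ci, agey, wt, cause_idx, site,
                           in_window) {
  n <- length(ci)
  if (n == 0L) return(invisible(tl))
  C <- P$C; Y <- P$Y
  in49 <- agey >= 15L & agey <= 49L
  tl$deaths_all_1549 <- .add_at(tl$deaths_all_1549,
                                .lin2(ci[in49], yi, C), wt[in49])
  pr <- in_window
  tl$preg_related <- .add_at(tl$preg_related, .lin2(ci[pr], yi, C), wt[pr])
  mat <- !is.na(cause_idx)
  if (any(mat)) {
    mi <- which(mat)
    tl$deaths_cause <- .add_at(tl$deaths_cause,
                               .lin3(ci[mi], yi, cause_idx[mi], C, Y), wt[mi])
    nl <- mi[cause_idx[mi] != 8L & in49[mi]] # non-late, ages 15-49
    tl$mat_deaths_age <- .add_at(tl$mat_deaths_age,
                                 .lin3(ci[nl], yi, agey[nl] - 14L, C, Y),
                                 wt[nl])
    # underreporting: independent capture per source given site and year
    st <- site[mi]
    for (s in 1:2) {
      cp <- P$capture[cbind(ci[mi], st, yi, s)]
      rp <- .bern(length(mi), cp)
      ri <- mi[rp]
      tl$reported <- .add_at(
        tl$reported,
        .lin3(ci[ri], yi, cause_idx[ri], C, Y) +
          (s - 1L) * C * Y * 8L, wt[ri])
    }
  }
  invisible(tl)
}

# ---------------------------------------------------------------------------
# referral cascade (three-delays): recognition -> transport -> target site,
# at most two hops, never downward; horizontal transfer allowed at BEmOC.

.cascade <- function(P, ci, yi, site, severe, rboost, ol_boost = 0) {
  k <- length(ci)
  req <- ifelse(severe, 5L, 4L)
  lg <- stats::qlogis(P$recog[site]) + P$recog_sev * severe + rboost + ol_boost
  rec <- .bern(k, stats::plogis(lg))
  fin <- site
  need <- rec & fin < req
  tr1 <- need & .bern(k, P$transport[fin])
  tgt <- ifelse(.bern(k, P$refc[fin]), 5L, 4L)
  fin[tr1] <- pmax(fin[tr1], tgt[tr1])
  need2 <- rec & fin < req & tr1
  tr2 <- need2 & .bern(k, P$transport[fin])
  fin[tr2] <- 5L
  fin
}

# ---------------------------------------------------------------------------
# one monthly cycle

#' Advance the population by one month
#'
#' Applies the canonical event order to every living woman and accumulates
#' events into the tally. Internal workhorse of [simulate_world()]; exposed
#' for testing and instrumentation.
#'
#' @param pop population environment from [init_population()].
#' @param P engine arrays.
#' @param tl tally environment (an `event_tally` converted with
#'   `list2env`); accumulated in place.
#' @param yi year index into `P$years`.
#' @param month calendar month 1--12.
#' @return The tally environment, invisibly (population and tally are
#'   modified in place).
#' @export
advance_month <- function(pop, P, tl, yi, month) {
  C <- P$C; Y <- P$Y
  n <- length(pop$ci)
  if (n > 0L) {
    ci <- pop$ci
    agey <- pop$age %/% 12L
    wt <- pop$w

    # (1) person-time and background mortality
    in49 <- agey >= 15L & agey <= 49L
    tl$py_age <- .add_at(tl$py_age,
                         .lin3(ci[in49], yi, agey[in49] - 14L, C, Y),
                         wt[in49] / 12)
    qm <- P$qm[.lin3(ci, pmin(agey, 59L) - 9L, yi, C, 50L)]
    dead <- which(.bern(n, qm))
    if (length(dead)) {
      win <- pop$preg[dead] | (pop$pp[dead] >= 0L & pop$pp[dead] <= 1L)
      cls <- classify_nonobstetric_death(win, P$p_injury[ci[dead]],
                                         P$p_indirect[ci[dead]])
      cidx <- rep(NA_integer_, length(dead))
      cidx[cls == "indirect"] <- 7L
      tl$flows[["pregnancies_interrupted"]] <-
        tl$flows[["pregnancies_interrupted"]] + sum(pop$preg[dead])
      .record_deaths(tl, P, yi, ci[dead], agey[dead], wt[dead], cidx,
                     rep(1L, length(dead)), win)
      pop$alive[dead] <- FALSE
    }
  }

  n <- length(pop$ci)
  if (n > 0L) {
    # (2) aging; women leaving the modelled age window (60y) exit the cohort
    pop$age <- pop$age + as.integer(pop$alive)
    pop$alive[pop$age >= 720L] <- FALSE
    ci <- pop$ci
    agey <- pop$age %/% 12L

    # (3) family planning
    act <- pop$alive & pop$age >= pop$debut & pop$age < pop$menop & !pop$preg
    pop$since_birth <- pop$since_birth + 1L
    old_int <- pop$intent
    intent <- 1L + (pop$since_birth < P$space_m)
    intent[pop$living >= pop$desired] <- 3L
    pop$intent <- intent
    chg <- which(intent != old_int | month == 1L | pop$pp == 1L)
    pop$pend[chg] <- TRUE
    # wants-soon: discontinue everything except permanent sterilisation
    ws <- which(act & intent == 1L & pop$meth > 0L & pop$meth != 3L)
    pop$meth[ws] <- 0L
    # method episode expiry for current users
    us <- which(act & pop$meth > 0L & pop$meth != 3L)
    if (length(us)) {
      pop$mon[us] <- pop$mon[us] + 1L
      ex <- us[pop$mon[us] >= pop$dur[us]]
      if (length(ex)) {
        sw <- ex[.bern(length(ex), P$switch)]
        st <- setdiff(ex, sw)
        pop$meth[st] <- 0L
        if (length(sw)) {
          mixrow <- 1L + (pop$intent[sw] == 3L)
          pop$meth[sw] <- .draw_method(mixrow, P)
          pop$mon[sw] <- 0L
          pop$dur[sw] <- .draw_duration(pop$meth[sw], pop$intent[sw], P)
        }
      }
    }
    # met-need evaluation for women with pending need
    ev <- which(act & pop$pend & pop$meth == 0L & intent > 1L)
    pop$pend[act] <- FALSE
    if (length(ev)) {
      met <- ev[.bern(length(ev), P$metneed[cbind(ci[ev], rep(yi, length(ev)))])]
      if (length(met)) {
        mixrow <- 1L + (pop$intent[met] == 3L)
        pop$meth[met] <- .draw_method(mixrow, P)
        pop$mon[met] <- 0L
        pop$dur[met] <- .draw_duration(pop$meth[met], pop$intent[met], P)
      }
    }

    # (4) conception
    el <- which(act & !pop$infert)
    if (length(el)) {
      band <- pmin((agey[el] - 10L) %/% 5L + 1L, 8L)
      fec <- P$fec[.lin2(ci[el], band, C)]
      fec[agey[el] >= 50L] <- 0
      lam <- rep(1, length(el))
      nursing <- pop$pp[el] >= 0L & pop$pp[el] <= 9L & pop$bfr[el] > 0L
      lam[nursing & pop$bfe[el]] <- P$lam_ex
      lam[nursing & !pop$bfe[el]] <- P$lam_pa
      pcon <- conception_prob(fec, lam, pop$meth[el] > 0L,
                              P$failm[pmax(pop$meth[el], 1L)])
      conc <- el[.bern(length(el), pcon)]
      if (length(conc)) {
        tl$flows[["conceptions"]] <- tl$flows[["conceptions"]] + length(conc)
        .start_pregnancy(pop, P, conc, yi)
      }
    }

    # (5) pregnancy-month update
    pr <- which(pop$preg & pop$alive)
    if (length(pr)) .pregnancy_month(pop, P, tl, pr, yi)

    # (6) postpartum update
    ppw <- which(pop$pp >= 0L & pop$alive)
    if (length(ppw)) {
      pop$pp[ppw] <- pop$pp[ppw] + 1L
      pop$bfr[ppw] <- pmax(pop$bfr[ppw] - 1L, 0L)
      lt <- ppw[pop$pp[ppw] >= 2L & pop$pp[ppw] <= 12L]
      if (length(lt)) {
        dd <- lt[.bern(length(lt), P$late[pop$ci[lt]])]
        if (length(dd)) {
          .record_deaths(tl, P, yi, pop$ci[dd], pop$age[dd] %/% 12L,
                         pop$w[dd], rep(8L, length(dd)),
                         rep(1L, length(dd)), rep(FALSE, length(dd)))
          pop$alive[dd] <- FALSE
          ppw <- which(pop$pp >= 0L & pop$alive)
        }
      }
      done <- ppw[pop$pp[ppw] > 12L]
      pop$pp[done] <- -1L
    }
  }

  # compact the dead / exited once per cycle
  if (length(pop$ci) && !all(pop$alive)) {
    .remove_women(pop, which(!pop$alive))
  }

  # (7) new entrants each January, at age 10 (pre-debut)
  if (month == 1L) {
    cnt <- P$entry[, yi]
    if (sum(cnt) > 0L) {
      ci_new <- rep(seq_len(C), cnt)
      new <- .init_women(P, ci_new, rep(120L, length(ci_new)))
      new$living <- integer(length(ci_new))
      new$since_birth <- rep(9999L, length(ci_new))
      .append_women(pop, new)
    }
  }
  invisible(tl)
}

.draw_method <- function(mixrow, P) {
  k <- length(mixrow)
  u <- stats::runif(k)
  cs <- P$mixcum
  m <- integer(k)
  for (r in 1:2) {
    j <- which(mixrow == r)
    if (length(j)) m[j] <- 1L + findInterval(u[j], cs[r, -4L])
  }
  m
}

.draw_duration <- function(meth, intent, P) {
  d <- rep(Inf, length(meth))
  sp <- intent == 2L & is.finite(P$durm[meth])
  d[sp] <- stats::rexp(sum(sp), 1 / P$durm[meth[sp]])
  d
}

.start_pregnancy <- function(pop, P, idx, yi) {
  k <- length(idx)
  ci <- pop$ci[idx]
  agey <- pop$age[idx] %/% 12L
  band <- pmin((agey - 10L) %/% 5L + 1L, 8L)
  pop$pp[idx] <- -1L
  pop$bfr[idx] <- 0L
  pop$preg[idx] <- TRUE
  pop$gest[idx] <- 0L
  twin <- .bern(k, P$twin[band])
  pop$nfet[idx] <- 1L + twin
  pop$nfem[idx] <- stats::rbinom(k, pop$nfet[idx], P$pF)
  pect <- pmin(1, P$ect[ci] * ifelse(pop$nect[idx] > 0L, P$ect_rr, 1))
  ect <- .bern(k, pect)
  pop$ect[idx] <- ect
  pop$nfet[idx][ect] <- 1L
  sched <- schedule_delivery(k, P$ddist)
  sched[ect] <- NA_integer_
  pop$sched[idx] <- sched
  pop$intended[idx] <- pop$intent[idx] == 1L
  pop$abdec[idx] <- FALSE
  # antenatal care: two-part (any visit, then zero-truncated Poisson count)
  anyv <- .bern(k, P$anc_any[cbind(ci, rep(yi, k))])
  visits <- integer(k)
  visits[anyv] <- .rztpois(sum(anyv), P$anc_l[ci[anyv]])
  pop$anc[idx] <- visits
  # ANC raises hemoglobin, capped at 16 g/dL without lowering high values
  hb <- pop$hb[idx]
  pop$hb[idx] <- pmin(hb + P$anc_hb * visits, pmax(hb, 16))
  pop$rboost[idx] <- P$anc_rb * visits
  invisible(pop)
}

.end_pregnancy <- function(pop, idx) {
  pop$preg[idx] <- FALSE
  pop$gest[idx] <- 0L
  pop$nfet[idx] <- 0L
  pop$nfem[idx] <- 0L
  pop$ect[idx] <- FALSE
  pop$sched[idx] <- 0L
  pop$rboost[idx] <- 0
  invisible(pop)
}

.pregnancy_month <- function(pop, P, tl, pr, yi) {
  C <- P$C
  pop$gest[pr] <- pop$gest[pr] + 1L
  g <- pop$gest[pr]

  # (a) ectopic resolution at gestational month 3 via the care pathway
  ei <- pr[pop$ect[pr] & g >= 3L]
  if (length(ei)) {
    tl$flows[["ectopics"]] <- tl$flows[["ectopics"]] + length(ei)
    ci <- pop$ci[ei]
    fin <- .cascade(P, ci, yi, rep(1L, length(ei)), rep(TRUE, length(ei)),
                    pop$rboost[ei])
    pd <- P$ectcfr[.lin2(ci, fin, C)] * P$ect_cure[cbind(ci, fin, yi)]
    died <- .bern(length(ei), pd)
    dd <- ei[died]
    if (length(dd)) {
      .record_deaths(tl, P, yi, pop$ci[dd], pop$age[dd] %/% 12L, pop$w[dd],
                     rep(6L, length(dd)), fin[died], rep(TRUE, length(dd)))
    }
    sv <- ei[!died]
    pop$nect[sv] <- pop$nect[sv] + 1L
    .end_pregnancy(pop, c(sv, dd))
    pop$alive[dd] <- FALSE
    pr <- which(pop$preg & pop$alive)
    g <- pop$gest[pr]
  }

  # (b) induced abortion decision (unintended pregnancies, first month)
  ai <- pr[!pop$intended[pr] & !pop$abdec[pr] & !pop$ect[pr] & g == 1L]
  if (length(ai)) {
    ci <- pop$ci[ai]
    pa <- P$abort[cbind(ci, rep(yi, length(ai)))]
    allf <- pop$nfem[ai] == pop$nfet[ai]
    fmult <- .sexsel_multiplier(pa, P$sr1, P$sr2[ci])
    pa <- pmin(1, pa * ifelse(allf, fmult, 1))
    dec <- .bern(length(ai), pa)
    pop$abdec[ai] <- TRUE
    ab <- ai[dec]
    if (length(ab)) {
      tl$flows[["abortions"]] <- tl$flows[["abortions"]] + length(ab)
      ci <- pop$ci[ab]
      safe <- .bern(length(ab), P$absafe[cbind(ci, rep(yi, length(ab)))])
      an <- is_anemic(pop$hb[ab], TRUE)
      pd <- ifelse(safe, 0, P$ucfr * ifelse(an, P$urr_an, 1))
      died <- .bern(length(ab), pd)
      dd <- ab[died]
      if (length(dd)) {
        .record_deaths(tl, P, yi, pop$ci[dd], pop$age[dd] %/% 12L, pop$w[dd],
                       rep(6L, length(dd)), rep(1L, length(dd)),
                       rep(TRUE, length(dd)))
      }
      sv <- ab[!died]
      pop$nab[sv] <- pop$nab[sv] + 1L
      pop$infert[sv] <- pop$infert[sv] |
        (!safe[!died] & .bern(length(sv), P$infert))
      .end_pregnancy(pop, c(sv, dd))
      pop$alive[dd] <- FALSE
      pr <- which(pop$preg & pop$alive)
      g <- pop$gest[pr]
    }
  }

  # (c) miscarriage, gestational months 1-5
  mi <- pr[!pop$ect[pr] & g >= 1L & g <= 5L]
  if (length(mi)) {
    h <- pmin(1, P$misc[pop$ci[mi]] *
                ifelse(pop$nmisc[mi] > 0L, P$misc_rr, 1))
    ms <- mi[.bern(length(mi), h)]
    if (length(ms)) {
      tl$flows[["miscarriages"]] <- tl$flows[["miscarriages"]] + length(ms)
      pop$nmisc[ms] <- pop$nmisc[ms] + 1L
      .end_pregnancy(pop, ms)
      pr <- which(pop$preg & pop$alive)
      g <- pop$gest[pr]
    }
  }

  # (d) antepartum stillbirth, months 6+, per fetus with male excess
  si <- pr[!pop$ect[pr] & g >= 6L]
  if (length(si)) {
    ci <- pop$ci[si]
    dF <- stats::rbinom(length(si), pop$nfem[si], P$sbf[ci])
    dM <- stats::rbinom(length(si), pop$nfet[si] - pop$nfem[si], P$sbm[ci])
    loss <- dF + dM
    if (any(loss > 0L)) {
      pop$nsb[si] <- pop$nsb[si] + loss
      pop$nfem[si] <- pop$nfem[si] - dF
      pop$nfet[si] <- pop$nfet[si] - loss
      gone <- si[pop$nfet[si] == 0L]
      if (length(gone)) {
        tl$flows[["stillbirth_terminations"]] <-
          tl$flows[["stillbirth_terminations"]] + length(gone)
        .end_pregnancy(pop, gone)
        pop$pp[gone] <- 0L # stillbirth delivery opens the postpartum window
        pr <- which(pop$preg & pop$alive)
      }
    }
  }

  # (e) delivery at the scheduled month
  dl <- pr[!pop$ect[pr] & pop$gest[pr] >= pop$sched[pr]]
  if (length(dl)) .delivery(pop, P, tl, dl, yi)
  invisible(tl)
}

# multiplier applied to the abortion probability of all-female pregnancies
# so that the birth sex ratio moves from the primary to the secondary sex
# ratio in expectation: f = (1 - (SR1/SR2) * (1 - a)) / a (clipped so that
# a*f stays in [0, 1]); equals 1 when SR2 == SR1.
.sexsel_multiplier <- function(a, sr1, sr2) {
  f <- ifelse(a > 0, (1 - (sr1 / sr2) * (1 - a)) / a, 1)
  pmax(0, pmin(f, ifelse(a > 0, 1 / a, 1)))
}

.delivery <- function(pop, P, tl, dl, yi) {
  C <- P$C; Y <- P$Y
  k <- length(dl)
  tl$flows[["deliveries"]] <- tl$flows[["deliveries"]] + k
  ci <- pop$ci[dl]
  sg <- pop$sg[dl]
  agey <- pop$age[dl] %/% 12L
  wt <- pop$w[dl]

  # starting site from the subgroup/year multinomial; elective C-section
  # only at EmOC facilities
  cum <- matrix(0, k, 4L)
  for (s in 1:4) cum[, s] <- P$sitecum[cbind(ci, sg, rep(yi, k), rep(s, k))]
  site <- 1L + rowSums(stats::runif(k) > cum)
  tl$site_deliv <- tl$site_deliv + tabulate(site, 5L)
  ecs <- .bern(k, P$ecs[cbind(ci, rep(yi, k))]) & site >= 4L

  an <- is_anemic(pop$hb[dl], TRUE)
  young <- agey < 20L
  old <- agey >= 35L
  multi <- pop$nfet[dl] >= 2L
  hist_pee <- pop$npee[dl] > 0L
  rr <- P$rr

  rmul <- function(rrv, flag) 1 + (rrv - 1) * flag
  p_pee <- P$cbase[.lin2(ci, rep(1L, k), C)] *
    rmul(rr$rr_pee_young, young) * rmul(rr$rr_pee_old, old) *
    rmul(rr$rr_pee_anemia, an) * rmul(rr$rr_pee_mult, multi) *
    rmul(rr$rr_pee_hist, hist_pee)
  p_ol <- P$cbase[.lin2(ci, rep(2L, k), C)] * rmul(rr$rr_ol_young, young)
  p_pph <- P$cbase[.lin2(ci, rep(3L, k), C)] *
    rmul(rr$rr_pph_anemia, an) * P$prev_pph[cbind(ci, site, yi)]
  p_sep <- P$cbase[.lin2(ci, rep(4L, k), C)] *
    rmul(rr$rr_sep_anemia, an) * rmul(rr$rr_sep_cs, ecs) *
    P$prev_sep[cbind(ci, site, yi)]
  p_oth <- P$cbase[.lin2(ci, rep(5L, k), C)]
  pmat <- cbind(p_pee, p_ol, p_pph, p_sep, p_oth)
  if (any(pmat > 1)) {
    if (is.null(P$warned_clip)) {
      warning("complication probability clipped to 1", call. = FALSE)
      P$warned_clip <- TRUE
    }
    pmat <- pmin(pmat, 1)
  }

  has <- matrix(FALSE, k, 5L)
  sev <- matrix(FALSE, k, 5L)
  fatal <- matrix(FALSE, k, 5L)
  fin_site <- matrix(site, k, 5L)
  for (tt in 1:5) {
    has[, tt] <- .bern(k, pmat[, tt])
    tl$comp_count[tt] <- tl$comp_count[tt] + sum(has[, tt])
    j <- which(has[, tt])
    if (!length(j)) next
    sev[j, tt] <- .bern(length(j), P$sevf[tt])
    olb <- if (tt == 2L) P$ol_recboost[cbind(ci[j], site[j], yi)] else 0
    fin <- .cascade(P, ci[j], yi, site[j], sev[j, tt], pop$rboost[dl][j], olb)
    fin_site[j, tt] <- fin
    pd <- P$cfr[cbind(ci[j], tt, 1L + sev[j, tt], fin)] *
      P$cure[cbind(ci[j], tt, fin, yi)]
    fatal[j, tt] <- .bern(length(j), pd)
  }

  # at most one maternal death per woman: first fatal cause in the fixed
  # priority order hemorrhage, sepsis, hypertensive, obstructed, other
  prio <- c(3L, 4L, 1L, 2L, 5L) # type indices in priority order
  cause_map <- c(3L, 4L, 1L, 2L, 5L) # type -> index in maternal_causes
  death_cause <- rep(NA_integer_, k)
  death_site <- site
  for (tt in prio) {
    sel <- is.na(death_cause) & fatal[, tt]
    death_cause[sel] <- cause_map[tt]
    death_site[sel] <- fin_site[sel, tt]
  }

  # severe complications never treated at an adequate site put each fetus
  # at intrapartum-stillbirth risk
  req <- ifelse(sev, 5L, 4L)
  unres <- rowSums(has & sev & fin_site < req) > 0L
  nfet <- pop$nfet[dl]
  nfem <- pop$nfem[dl]
  ipF <- integer(k); ipM <- integer(k)
  j <- which(unres)
  if (length(j)) {
    ipF[j] <- stats::rbinom(length(j), nfem[j], P$ipsb)
    ipM[j] <- stats::rbinom(length(j), nfet[j] - nfem[j], P$ipsb)
  }
  born <- nfet - ipF - ipM
  bornF <- nfem - ipF
  tl$flows[["births_f"]] <- tl$flows[["births_f"]] + sum(bornF)
  tl$flows[["births_m"]] <- tl$flows[["births_m"]] + sum(born - bornF)
  pop$nsb[dl] <- pop$nsb[dl] + ipF + ipM

  tl$live_births <- .add_at(tl$live_births, .lin2(ci, yi, C), wt * born)

  died <- !is.na(death_cause)
  dd <- dl[died]
  if (length(dd)) {
    .record_deaths(tl, P, yi, ci[died], agey[died], wt[died],
                   death_cause[died], death_site[died],
                   rep(TRUE, length(dd)))
  }

  sv <- dl[!died]
  svk <- which(!died)
  if (length(sv)) {
    pop$living[sv] <- pop$living[sv] + born[svk]
    pop$npee[sv] <- pop$npee[sv] + has[svk, 1L]
    pop$ncs[sv] <- pop$ncs[sv] +
      (ecs[svk] | (has[svk, 2L] & fin_site[svk, 2L] == 5L))
    pop$since_birth[sv[born[svk] > 0L]] <- 0L
    .end_pregnancy(pop, sv)
    pop$pp[sv] <- 0L
    bf <- .bern(length(sv), P$bf_prob[pop$ci[sv]]) & born[svk] > 0L
    pop$bfe[sv] <- bf & .bern(length(sv), P$bf_excl[pop$ci[sv]])
    bfr <- integer(length(sv))
    bfr[bf] <- 1L + stats::rgeom(sum(bf), 1 / P$bf_mean)
    pop$bfr[sv] <- bfr
  }
  .end_pregnancy(pop, dd)
  pop$alive[dd] <- FALSE
  invisible(tl)
}

# ---------------------------------------------------------------------------

#' Run the microsimulation
#'
#' Simulates the world's population month by month over the requested years
#' under a given parameter set and returns the event tally (scaled by
#' `persons_per_agent`). Deterministic given `(world, pset, seed)`.
#'
#' @param world a world from [generate_synthetic_world()].
#' @param pset a `parameter_set`.
#' @param seed integer seed for the run's random stream.
#' @param years years to simulate (default all of the world's years,
#'   including burn-in).
#' @param n_agents initial women per country (default the world's).
#' @return An `event_tally` covering the simulated years.
#' @export
simulate_world <- function(world, pset, seed, years = world$years,
                           n_agents = world$n_agents) {
  stopifnot(.is_count(seed))
  set.seed(seed)
  P <- build_engine_params(world, pset, years)
  pop <- init_population(world, P, n_agents)
  tl <- list2env(unclass(new_event_tally(world$countries, years)),
                 parent = emptyenv())
  tl$flows <- c(conceptions = 0, miscarriages = 0, ectopics = 0,
                abortions = 0, stillbirth_terminations = 0, deliveries = 0,
                pregnancies_interrupted = 0, births_f = 0, births_m = 0)
  tl$site_deliv <- numeric(5L)
  tl$comp_count <- numeric(5L)
  for (yi in seq_along(years)) {
    for (m in 1:12) {
      advance_month(pop, P, tl, yi, m)
    }
  }
  out <- new_event_tally(world$countries, years)
  for (f in c("live_births", "deaths_cause", "mat_deaths_age",
              "preg_related", "deaths_all_1549", "py_age", "reported")) {
    out[[f]] <- tl[[f]] * P$ppa
  }
  attr(out, "final_population") <- length(pop$ci)
  attr(out, "flows") <- tl$flows
  attr(out, "site_deliveries") <- tl$site_deliv
  attr(out, "complication_counts") <- tl$comp_count
  attr(out, "ongoing_pregnancies") <- sum(pop$preg)
  out
}
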