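#' Default hierarchical prior catalogue for country-varying parameters
#'
#' Priors for the parameters that vary across countries in the synthetic
#' world. Each is a five-level [parameter_prior()]; the generator draws one
#' normal offset per hierarchy node and resolves country values along
#' ancestor paths, so countries sharing a region/continent/income group are
#' correlated, mimicking hierarchical shrinkage structure.
#'
#' Scales follow the package convention: probabilities on logit, rates and
#' multipliers on log, unbounded shifts on identity.
#'
#' @return Named list of [parameter_prior()] objects.
#' @export
default_priors <- function() {
  pp <- function(name, scale, mean, sds, bounds = NULL) {
    parameter_prior(name, scale, c(mean, 0, 0, 0, 0), sds, bounds)
  }
  # dispersion vectors: (global, income_group, continent, region, country)
  sd_med <- c(0, 0.25, 0.15, 0.10, 0.20)
  sd_sml <- c(0, 0.15, 0.10, 0.08, 0.12)
  list(
    mort_mult = pp("demog.mort_mult", "log", log(1.0), sd_med, c(0.4, 2.5)),
    p_indirect = pp("demog.p_indirect", "logit", stats::qlogis(0.20), sd_med),
    fec_mult = pp("bio.fec_mult", "log", log(1.0), sd_sml, c(0.6, 1.5)),
    hb_shift = pp("bio.hb_shift", "identity", 0, c(0, 0.4, 0.25, 0.15, 0.3),
                  c(-2, 2)),
    dfs_lambda = pp("fp.dfs_lambda", "log", log(3.2), sd_med, c(1.2, 6)),
    metneed_b = pp("fp.metneed_b", "logit", stats::qlogis(0.45), sd_med),
    abortion_b = pp("fp.abortion_b", "logit", stats::qlogis(0.18), sd_med),
    abortion_safe_b = pp("fp.abortion_safe_b", "logit", stats::qlogis(0.55),
                         sd_med),
    anc_any_b = pp("hs.anc_any_b", "logit", stats::qlogis(0.70), sd_med),
    facility_shift = pp("hs.facility_shift", "identity", 0,
                        c(0, 0.8, 0.4, 0.3, 0.5), c(-3, 3)),
    quality_shift = pp("hs.quality_shift", "identity", 0,
                       c(0, 0.6, 0.3, 0.2, 0.4), c(-2.5, 2.5)),
    capture_b = pp("hs.capture_b", "logit", stats::qlogis(0.55),
                   c(0, 0.7, 0.3, 0.2, 0.4)),
    cfr_shift = pp("comp.cfr_shift", "identity", 0,
                   c(0, 0.4, 0.25, 0.15, 0.3), c(-2, 2)),
    late_hazard = pp("comp.late_hazard", "log", log(2e-4), sd_med,
                     c(2e-5, 2e-3)),
    sr_secondary = pp("fp.sr_secondary", "log", log(1.05),
                      c(0, 0.01, 0.005, 0.005, 0.015), c(1.0, 1.20))
  )
}

# draw one offset per hierarchy node for a prior; returns named vector
.draw_node_offsets <- function(prior, hierarchy) {
  sds <- prior$level_sds[hierarchy$level]
  stats::setNames(stats::rnorm(nrow(hierarchy), 0, sds), hierarchy$id)
}

# resolve a prior for every country given per-node offsets
.resolve_countries <- function(prior, hierarchy, node_offsets) {
  vapply(countries_of(hierarchy), function(cty) {
    path <- country_path(hierarchy, cty)
    resolve_parameter(prior, stats::setNames(node_offsets[path], .geo_levels))
  }, numeric(1))
}

# small synthetic hierarchy: countries round-robined over 2 income groups,
# 2 continents, and one region per (income group, continent) pair
.synthetic_hierarchy <- function(n_countries) {
  igs <- c("LIC", "MIC")
  conts <- c("AFR", "ASI")
  nodes <- data.frame(id = "GLB", level = "global", parent = NA_character_)
  for (g in igs) nodes <- rbind(nodes, data.frame(id = g, level = "income_group",
                                                  parent = "GLB"))
  for (g in igs) for (ct in conts) {
    nodes <- rbind(nodes, data.frame(id = paste(g, ct, sep = "."),
                                     level = "continent", parent = g))
    nodes <- rbind(nodes, data.frame(id = paste(g, ct, "R1", sep = "."),
                                     level = "region",
                                     parent = paste(g, ct, sep = ".")))
  }
  regions <- nodes$id[nodes$level == "region"]
  ctys <- sprintf("C%02d", seq_len(n_countries))
  nodes <- rbind(nodes, data.frame(
    id = ctys, level = "country",
    parent = regions[((seq_len(n_countries) - 1L) %% length(regions)) + 1L]))
  geo_hierarchy(nodes)
}

#' Generate a self-consistent synthetic world with known ground truth
#'
#' Builds a small multi-country world in the shape of the real inputs the
#' simulator is designed around: UN-style female lifetables and entry
#' cohorts, DHS-style subgroup (urban/rural x 3 education levels)
#' composition, family-planning and health-system parameters, and
#' complication/case-fatality parameters -- all drawn through the
#' hierarchical prior catalogue so that the exact truth is recorded and can
#' later be targeted by calibration. No real data source is read; the
#' generator emulates the *structure* of those inputs at desk scale.
#'
#' @param n_countries number of countries (>= 1).
#' @param seed integer RNG seed; regeneration under the same seed is
#'   bit-identical.
#' @param years simulated calendar years (first years serve as burn-in).
#' @param report_from first reporting year (after burn-in).
#' @param n_agents initial simulated women per country (ages 10--54).
#' @param entry_rate annual new entrants (at age 10) as a fraction of
#'   `n_agents`.
#' @param persons_per_agent population scale factor applied to tallies.
#' @return List with elements `world` (configuration + lifetables +
#'   subgroup shares + entry schedule) and `truth` (the exact
#'   `parameter_set` used; see [simulate_world()]).
#' @export
generate_synthetic_world <- function(n_countries, seed,
                                     years = 1985:2020, report_from = 1990,
                                     n_agents = 1000L, entry_rate = 0.03,
                                     persons_per_agent = 1) {
  stopifnot(.is_count(n_countries), n_countries >= 1, .is_count(seed),
            n_agents >= 10, entry_rate >= 0,
            report_from > min(years), report_from <= max(years))
  set.seed(seed)
  hierarchy <- .synthetic_hierarchy(n_countries)
  ctys <- countries_of(hierarchy)
  C <- n_countries
  Y <- length(years)

  priors <- default_priors()
  drawn <- lapply(priors, function(p) {
    .resolve_countries(p, hierarchy, .draw_node_offsets(p, hierarchy))
  })

  # --- demography -----------------------------------------------------
  ages <- 10:59
  base_q <- 3e-4 + 6e-6 * (ages - 10)^2 # female annual all-cause risk
  lifetable <- array(0, c(C, length(ages), Y),
                     dimnames = list(ctys, as.character(ages),
                                     as.character(years)))
  for (ci in seq_len(C)) {
    for (yi in seq_len(Y)) {
      lifetable[ci, , yi] <- pmin(
        drawn$mort_mult[ci] * base_q * 0.99^(yi - 1), 0.5)
    }
  }
  p_injury <- .clip(stats::rnorm(C, 0.12, 0.02), 0.03, 0.3)

  shares0 <- c(0.12, 0.16, 0.12, 0.22, 0.23, 0.15) # urban x3 edu, rural x3 edu
  subgroup_shares <- t(vapply(seq_len(C), function(ci) {
    g <- stats::rgamma(6, shape = 40 * shares0)
    g / sum(g)
  }, numeric(6)))
  dimnames(subgroup_shares) <- list(ctys, .subgroup_names)

  entry_schedule <- matrix(max(1L, round(n_agents * entry_rate)), C, Y,
                           dimnames = list(ctys, as.character(years)))

  # --- ground-truth parameter set -------------------------------------
  edu_hb <- rep(c(0, 0.3, 0.6), 2) + rep(c(0.25, 0), each = 3) # urban bonus
  hb_mean <- outer(11.9 + drawn$hb_shift, edu_hb, `+`)
  dimnames(hb_mean) <- list(ctys, .subgroup_names)

  debut_shift <- rep(c(0, 6, 14), 2) + rep(c(4, 0), each = 3) # months
  debut_median <- outer(rep(206, C) + stats::rnorm(C, 0, 6), debut_shift, `+`)
  dimnames(debut_median) <- list(ctys, .subgroup_names)

  site_base_logit <- cbind(
    1.2 - drawn$facility_shift,   # Home
    0.0,                          # Home-SBA
    -0.4 + 0.3 * drawn$facility_shift,
    -0.6 + 0.8 * drawn$facility_shift,
    -1.4 + 1.0 * drawn$facility_shift)
  dimnames(site_base_logit) <- list(ctys, .site_names)

  cfr_severe <- rbind(
    pe_eclampsia = c(0.12, 0.10, 0.07, 0.030, 0.012),
    obstructed_labor = c(0.08, 0.07, 0.05, 0.020, 0.008),
    pph = c(0.22, 0.18, 0.12, 0.050, 0.020),
    sepsis = c(0.15, 0.12, 0.09, 0.040, 0.015),
    other_direct = c(0.05, 0.04, 0.03, 0.015, 0.006))
  colnames(cfr_severe) <- .site_names

  interv <- list(
    amtsl = list(kind = "preventive", target = "pph", min_site = 2L,
                 efficacy = 0.40),
    clean_delivery = list(kind = "preventive", target = "sepsis",
                          min_site = 2L, efficacy = 0.50),
    partograph = list(kind = "recognition", target = "obstructed_labor",
                      min_site = 3L, boost_logit = 0.8),
    ectopic_mgmt = list(kind = "curative", target = "ectopic", min_site = 4L,
                        efficacy = 0.08),
    hypertension_mgmt = list(kind = "curative", target = "pe_eclampsia",
                             min_site = 3L, efficacy = 0.30),
    assisted_delivery = list(kind = "curative", target = "obstructed_labor",
                             min_site = 4L, efficacy = 0.35),
    hemorrhage_mgmt = list(kind = "curative", target = "pph", min_site = 4L,
                           efficacy = 0.25),
    antibiotics = list(kind = "curative", target = "sepsis", min_site = 3L,
                       efficacy = 0.30))
  avail_base <- c(0.05, 0.35, 0.55, 0.75, 0.90)
  for (nm in names(interv)) {
    interv[[nm]]$avail_base <- avail_base
    interv[[nm]]$avail_slope <- 0.02 # logit per year
  }

  truth <- structure(list(
    demog = list(p_indirect = drawn$p_indirect),
    bio = list(
      fec_band = outer(drawn$fec_mult,
                       c(0.01, 0.13, 0.20, 0.18, 0.14, 0.09, 0.03, 0.006)),
      twin_mono = 0.004,
      twin_di = c(0, 0.002, 0.004, 0.007, 0.010, 0.013, 0.010, 0.005),
      sr_primary = 1.05,
      sr_secondary = drawn$sr_secondary,
      misc_base = .clip(0.020 * drawn$mort_mult^0.3, 0.005, 0.06),
      misc_rr_hist = 1.8,
      ect_base = rep(0.015, C),
      ect_rr_recur = 3,
      sb_base = .clip(0.004 * drawn$mort_mult^0.5, 0.001, 0.02),
      sb_rr_male = 1.1,
      delivery_dist = c(0.04, 0.10, 0.72, 0.14),
      lam_excl_mult = 0.15, lam_part_mult = 0.60,
      menop_mean_m = 600, menop_sd_m = 42,
      hb_mean = hb_mean, hb_sd = 1.3,
      bf_prob = rep(0.90, C), bf_excl_prob = rep(0.55, C),
      bf_mean_months = 12),
    fp = list(
      debut_median_m = debut_median, debut_logsd = 0.10,
      dfs_w = rep(0.25, C), dfs_kstar = 2L, dfs_lambda = drawn$dfs_lambda,
      spacing_months = 24L,
      metneed_b = .fwd(drawn$metneed_b, "logit"),
      metneed_slope = rep(0.04, C), metneed_alpha = 1,
      mix_spacing = c(short_acting = 0.55, long_acting = 0.25,
                      permanent = 0, traditional = 0.20),
      mix_limiting = c(short_acting = 0.30, long_acting = 0.40,
                       permanent = 0.20, traditional = 0.10),
      fail_annual = c(short_acting = 0.09, long_acting = 0.01,
                      permanent = 0.003, traditional = 0.20),
      dur_mean = c(short_acting = 24, long_acting = 48,
                   permanent = Inf, traditional = 18),
      switch_prob = 0.35,
      abortion_b = .fwd(drawn$abortion_b, "logit"),
      abortion_slope = rep(0, C), abortion_alpha = 1,
      abortion_safe_b = .fwd(drawn$abortion_safe_b, "logit"),
      abortion_safe_slope = rep(0.03, C),
      unsafe_cfr = 0.015, unsafe_rr_anemia = 1.5, infert_prob = 0.05),
    hs = list(
      anc_any_b = .fwd(drawn$anc_any_b, "logit"),
      anc_any_slope = rep(0.03, C),
      anc_lambda = rep(3, C),
      anc_hb_coef = 0.08, anc_recog_coef = 0.15,
      site_base_logit = site_base_logit,
      site_trend_slope = rep(0.03, C),
      sg_facility_shift = c(0.5, 0.8, 1.2, 0, 0.3, 0.7), # by subgroup
      ecs_b = rep(.fwd(0.03, "logit"), C), ecs_slope = rep(0.05, C),
      recog_base = c(0.35, 0.50, 0.60, 0.75, 0.85),
      recog_sev_boost = 1.0,
      transport = c(0.55, 0.60, 0.70, 0.80, 0.90),
      ref_p_cemoc = c(0.30, 0.30, 0.40, 0.80, 1.0),
      quality_base = .clip(outer(drawn$quality_shift * 0.15,
                                 c(0.20, 0.30, 0.45, 0.65, 0.85), `+`),
                           0.05, 0.98),
      quality_slope = rep(0.01, C), # natural-scale logit slope via rebuild
      capture_b = .fwd(drawn$capture_b, "logit"),
      capture_site_shift = c(-0.8, -0.3, 0.3, 0.9, 1.5),
      capture_slope = rep(0.04, C),
      survey_boost = 0.7),
    comp = list(
      base = outer(rep(1, C), c(pe_eclampsia = 0.035, obstructed_labor = 0.045,
                                pph = 0.060, sepsis = 0.030,
                                other_direct = 0.020)),
      rr_pee_young = 1.5, rr_pee_old = 1.6, rr_pee_anemia = 1.3,
      rr_pee_mult = 2.5, rr_pee_hist = 3.0,
      rr_ol_young = 1.4,
      rr_pph_anemia = 1.8,
      rr_sep_anemia = 1.5, rr_sep_cs = 2.0,
      sev_frac = c(0.25, 0.30, 0.30, 0.30, 1.0),
      cfr_severe = cfr_severe,
      cfr_nonsev_frac = 0.12,
      cfr_shift = drawn$cfr_shift,
      ect_cfr = c(0.18, 0.15, 0.10, 0.04, 0.015),
      ip_sb_prob = 0.25,
      late_hazard = drawn$late_hazard),
    interv = interv
  ), class = "parameter_set")
  rownames(truth$comp$base) <- ctys

  world <- list(
    hierarchy = hierarchy, countries = ctys,
    years = as.integer(years), report_from = as.integer(report_from),
    n_agents = as.integer(n_agents),
    persons_per_agent = persons_per_agent,
    entry_schedule = entry_schedule,
    lifetable = lifetable, p_injury = p_injury,
    subgroup_shares = subgroup_shares,
    seed = as.integer(seed))
  class(world) <- "ms_world"
  list(world = world, truth = truth)
}

.subgroup_names <- c("urban_low", "urban_middle", "urban_high",
                     "rural_low", "rural_middle", "rural_high")
.site_names <- c("Home", "Home_SBA", "nonEmOC", "BEmOC", "CEmOC")

#' Generate synthetic calibration targets from a known truth
#'
#' Runs the engine under the ground-truth parameter set and turns its
#' *reported* death counts (after underreporting) into calibration targets,
#' mimicking CRVS-style reported maternal deaths, total and by the eight
#' grouped causes. Gaussian observation noise of the stated standard
#' deviation is added (truncated at zero) and targets are tagged
#' train/test by the cut year.
#'
#' @param world,truth from [generate_synthetic_world()].
#' @param reps simulation replicates averaged per target (>= 1).
#' @param noise_sd standard deviation of additive observation noise (>= 0).
#' @param seed integer RNG seed.
#' @param cut_year last training year (default: 5 years before the end).
#' @param source reporting source emulated (`"CRVS"` or `"survey"`).
#' @return data.frame of targets: country, year, indicator, cause, value,
#'   source, split, weight.
#' @export
generate_synthetic_targets <- function(world, truth, reps = 2L, noise_sd = 1,
                                       seed = 1L,
                                       cut_year = max(world$report_from,
                                                      max(world$years) - 5L),
                                       source = "CRVS") {
  stopifnot(.is_count(reps), reps >= 1)
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be >= 0", call. = FALSE)
  }
  source <- match.arg(source, .report_sources)
  si <- match(source, .report_sources)
  yrs <- world$years[world$years >= world$report_from]
  acc <- 0
  for (r in seq_len(reps)) {
    tl <- simulate_world(world, truth, seed = seed + 1000L * r)
    yi <- match(yrs, tl$years)
    arr <- tl$reported[, yi, , si, drop = FALSE]
    dim(arr) <- dim(arr)[1:3]
    acc <- acc + arr
  }
  rep_mean <- acc / reps # [C, years, 8 causes]
  C <- length(world$countries)
  grid <- expand.grid(country = world$countries, year = yrs,
                      cause = c("total", maternal_causes),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  set.seed(seed)
  val <- mapply(function(cty, yr, cs) {
    ci <- match(cty, world$countries); yi <- match(yr, yrs)
    if (cs == "total") sum(rep_mean[ci, yi, ]) else
      rep_mean[ci, yi, match(cs, maternal_causes)]
  }, grid$country, grid$year, grid$cause)
  grid$indicator <- "reported_maternal_deaths"
  grid$value <- pmax(0, val + stats::rnorm(nrow(grid), 0, noise_sd))
  grid$source <- source
  grid$weight <- 1
  grid <- grid[, c("country", "year", "indicator", "cause", "value",
                   "source", "weight")]
  train_test_split(grid, cut_year)
}
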