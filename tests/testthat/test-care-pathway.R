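# Antenatal care, delivery-site choice, complication incidence, the
# recognition -> transport -> referral cascade, intervention effectiveness,
# death resolution and underreporting.

# a pset where deliveries happen fast and often, with no other noise
fertile_base <- function(g, f = 0.25) {
  early_debut(no_contraception(fixed_fecundity(quiet_pset(g$truth), f)))
}

test_that("antenatal care is two-part and shifts hemoglobin linearly", {
  g <- solo_world()
  truth <- no_anc(quiet_pset(g$truth))
  P <- build_engine_params(g$world, truth)
  set.seed(1)
  n <- 5000
  pop <- init_population(g$world, P, n)
  pop$age[] <- 300L
  hb0 <- pop$hb
  maternalsim:::.start_pregnancy(pop, P, seq_len(n), 1L)
  expect_true(all(pop$anc == 0L))
  expect_true(all(pop$rboost == 0))
  expect_equal(pop$hb, hb0) # no visits, no effect

  # certain attendance, zero-truncated Poisson visit count
  truth2 <- quiet_pset(g$truth)
  truth2$hs$anc_any_b[] <- 50
  truth2$hs$anc_any_slope[] <- 0
  truth2$hs$anc_lambda[] <- 4
  truth2$hs$anc_hb_coef <- 0.1
  P2 <- build_engine_params(g$world, truth2)
  set.seed(2)
  n2 <- 1e5
  pop2 <- init_population(g$world, P2, n2)
  pop2$age[] <- 300L
  pop2$hb[] <- 10
  maternalsim:::.start_pregnancy(pop2, P2, seq_len(n2), 1L)
  m_exp <- 4 / (1 - exp(-4))
  se <- sqrt(m_exp / n2) # Poisson-scale spread is adequate here
  expect_lt(abs(mean(pop2$anc) - m_exp), 3 * se)
  expect_true(all(pop2$anc >= 1L))
  # per-visit effects are exactly linear
  expect_equal(pop2$hb, pmin(10 + 0.1 * pop2$anc, 16))
  expect_equal(pop2$rboost, truth2$hs$anc_recog_coef * pop2$anc)
})

test_that("delivery sites follow the configured multinomial", {
  g <- solo_world()
  truth <- fertile_base(g)
  truth$hs$sg_facility_shift[] <- 0
  truth$hs$site_trend_slope[] <- 0
  lg <- c(1.0, 0.5, 0, -0.5, -1.0)
  truth$hs$site_base_logit[] <- rep(lg, each = 1)
  p_exp <- exp(lg) / sum(exp(lg))
  tl <- simulate_world(no_entrants(flat_mortality(g$world, 0)), truth,
                       seed = 3, years = 2000:2004, n_agents = 1500)
  sd_ <- attr(tl, "site_deliveries")
  n <- sum(sd_)
  expect_gt(n, 3000)
  for (s in 1:5) {
    se <- sqrt(p_exp[s] * (1 - p_exp[s]) / n)
    expect_lt(abs(sd_[s] / n - p_exp[s]), 3.5 * se)
  }
})

test_that("elective C-sections only happen at EmOC facilities", {
  g <- solo_world()
  truth <- home_delivery_only(fertile_base(g))
  truth$hs$ecs_b[] <- 50 # would be certain, but the site gate blocks it
  P <- build_engine_params(no_entrants(flat_mortality(g$world, 0)), truth)
  tl <- simulate_world(no_entrants(flat_mortality(g$world, 0)), truth,
                       seed = 4, years = 2000:2003)
  expect_gt(attr(tl, "flows")[["deliveries"]], 0)
  expect_equal(attr(tl, "site_deliveries")[2:5], rep(0, 4))
  # sepsis C-section risk factor can never fire at home
  expect_equal(sum(attr(tl, "complication_counts")), 0) # quiet comp base
})

test_that("complication risk multipliers act multiplicatively", {
  g <- solo_world()
  world <- no_entrants(flat_mortality(g$world, 0))
  base <- home_delivery_only(no_interventions(no_recognition(
    fertile_base(g))))
  base$comp$cfr_severe[] <- 0
  base$comp$base[] <- 0
  base$comp$base[, 3] <- 0.05 # hemorrhage only
  base$comp$rr_pph_anemia <- 2

  run_inc <- function(hb, seed) {
    tt <- base
    tt$bio$hb_mean[] <- hb
    tt$bio$hb_sd <- 1e-6
    tl <- simulate_world(world, tt, seed = seed, years = 2000:2004)
    c(inc = attr(tl, "complication_counts")[3] /
        attr(tl, "flows")[["deliveries"]],
      n = attr(tl, "flows")[["deliveries"]])
  }
  r_an <- run_inc(8, 5)   # anemic in pregnancy (< 11 g/dL)
  r_ok <- run_inc(15, 6)  # not anemic
  se_an <- sqrt(0.10 * 0.90 / r_an[["n"]])
  se_ok <- sqrt(0.05 * 0.95 / r_ok[["n"]])
  expect_lt(abs(r_an[["inc"]] - 0.10), 3 * se_an)
  expect_lt(abs(r_ok[["inc"]] - 0.05), 3 * se_ok)
})

test_that("preventive interventions scale incidence by their effectiveness", {
  g <- solo_world()
  world <- no_entrants(flat_mortality(g$world, 0))
  base <- home_delivery_only(no_recognition(fertile_base(g)))
  base$comp$cfr_severe[] <- 0
  base$comp$base[] <- 0
  base$comp$base[, 3] <- 0.10
  base$comp$rr_pph_anemia <- 1
  base$hs$quality_base[] <- 0.999999 # kappa = 1
  base$hs$quality_slope[] <- 0
  for (nm in names(base$interv)) base$interv[[nm]]$avail_base <- rep(0, 5)

  with_amtsl <- base
  with_amtsl$interv$amtsl$avail_base <- rep(1, 5)
  with_amtsl$interv$amtsl$avail_slope <- 0
  with_amtsl$interv$amtsl$min_site <- 1L
  with_amtsl$interv$amtsl$efficacy <- 0.4 # incidence RR applied = 0.4

  inc <- function(tt, seed) {
    tl <- simulate_world(world, tt, seed = seed, years = 2000:2004)
    c(p = attr(tl, "complication_counts")[3] /
        attr(tl, "flows")[["deliveries"]],
      n = attr(tl, "flows")[["deliveries"]])
  }
  r0 <- inc(base, 7)
  r1 <- inc(with_amtsl, 8)
  p0 <- 0.10; p1 <- 0.04
  expect_lt(abs(r0[["p"]] - p0), 3 * sqrt(p0 * (1 - p0) / r0[["n"]]))
  expect_lt(abs(r1[["p"]] - p1), 3 * sqrt(p1 * (1 - p1) / r1[["n"]]))
})

test_that("the referral cascade multiplies recognition and transport", {
  P <- new.env()
  P$recog <- rep(0.8, 5)
  P$recog_sev <- 0
  P$transport <- rep(0.5, 5)
  P$refc <- rep(1, 5) # always target CEmOC
  set.seed(9)
  n <- 1e5
  fin <- maternalsim:::.cascade(P, rep(1L, n), 1L, rep(1L, n),
                                rep(TRUE, n), rep(0, n))
  arrived <- mean(fin == 5L)
  expect_lt(abs(arrived - 0.4), 3 * sqrt(0.4 * 0.6 / n))
  expect_true(all(fin %in% c(1L, 5L)))

  # no recognition: treated where you are
  P$recog <- rep(1e-12, 5)
  fin0 <- maternalsim:::.cascade(P, rep(1L, n), 1L, rep(2L, n),
                                 rep(TRUE, n), rep(0, n))
  expect_true(all(fin0 == 2L))

  # certain recognition + transport to a CEmOC point target
  P$recog <- rep(1, 5)
  P$transport <- rep(1, 5)
  fin1 <- maternalsim:::.cascade(P, rep(1L, 100), 1L, rep(1L, 100),
                                 rep(TRUE, 100), rep(0, 100))
  expect_true(all(fin1 == 5L))
  # referral never moves a woman to a lower-capability site
  P$recog <- rep(0.7, 5); P$transport <- rep(0.6, 5); P$refc <- rep(0.5, 5)
  set.seed(10)
  start <- sample(1:5, 1e4, replace = TRUE)
  sev <- runif(1e4) < 0.5
  fin2 <- maternalsim:::.cascade(P, rep(1L, 1e4), 1L, start, sev,
                                 rep(0, 1e4))
  expect_true(all(fin2 >= start))
})

test_that("effectiveness interpolates between no effect and full efficacy", {
  expect_equal(effectiveness(1, 1, 0.3), 0.3)
  expect_equal(effectiveness(0, 1, 0.3), 1)
  expect_equal(effectiveness(0.8, 0.5, 0.3), 0.72, tolerance = 1e-9)
  expect_equal(effectiveness(1, 1, 0.3, applicable = FALSE), 1)
  expect_error(effectiveness(1.2, 1, 0.3), "\\[0, 1\\]")
  # applied RR always within [efficacy, 1]
  set.seed(11)
  a <- runif(100); q <- runif(100); e <- runif(100)
  rr <- effectiveness(a, q, e)
  expect_true(all(rr >= e - 1e-12 & rr <= 1 + 1e-12))
})

test_that("case fatality composes CFR and curative effectiveness", {
  g <- solo_world()
  world <- no_entrants(flat_mortality(g$world, 0))
  tt <- home_delivery_only(no_recognition(fertile_base(g)))
  tt$comp$base[] <- 0
  tt$comp$base[, 3] <- 1 # certain severe hemorrhage
  tt$comp$sev_frac[] <- 1
  tt$comp$cfr_severe[] <- 0
  tt$comp$cfr_severe[3, 1] <- 0.1 # at Home
  tt$comp$cfr_shift[] <- 0
  tt$hs$quality_base[] <- 0.999999
  tt$hs$quality_slope[] <- 0
  for (nm in names(tt$interv)) tt$interv[[nm]]$avail_base <- rep(0, 5)
  tt$interv$hemorrhage_mgmt$avail_base <- rep(1, 5)
  tt$interv$hemorrhage_mgmt$avail_slope <- 0
  tt$interv$hemorrhage_mgmt$min_site <- 1L
  tt$interv$hemorrhage_mgmt$efficacy <- 0.2
  tt$comp$ip_sb_prob <- 0

  tl <- simulate_world(world, tt, seed = 12, years = 2000:2005,
                       n_agents = 1500)
  n <- attr(tl, "flows")[["deliveries"]]
  deaths <- sum(tl$deaths_cause[, , 1]) # hemorrhage
  p <- 0.1 * 0.2
  expect_gt(n, 4000)
  expect_lt(abs(deaths / n - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("at most one maternal death per delivery, in cause priority order", {
  g <- solo_world()
  world <- no_entrants(flat_mortality(g$world, 0))
  tt <- home_delivery_only(no_interventions(no_recognition(fertile_base(g))))
  tt$comp$base[] <- 0
  tt$comp$base[, 1] <- 1 # pre-eclampsia/eclampsia, certain
  tt$comp$base[, 3] <- 1 # hemorrhage, certain
  tt$comp$sev_frac[] <- 1
  tt$comp$cfr_severe[] <- 1
  tt$comp$cfr_shift[] <- 0
  tt$comp$ip_sb_prob <- 0
  tl <- simulate_world(world, tt, seed = 13, years = 2000:2002,
                       n_agents = 1200)
  n <- attr(tl, "flows")[["deliveries"]]
  expect_gt(n, 500)
  # every delivering woman dies exactly once, attributed to hemorrhage
  expect_equal(sum(tl$deaths_cause[, , 1]), n)
  expect_equal(sum(tl$deaths_cause[, , 3]), 0)
  expect_equal(sum(tl$deaths_cause[, , 1:7]), n)
})

test_that("late maternal hazard accumulates over postpartum cycles 2-12", {
  g <- solo_world()
  world <- no_entrants(flat_mortality(g$world, 0))
  tt <- early_debut(quiet_pset(g$truth))
  tt$bio$fec_band[] <- 0.25
  tt$bio$twin_mono <- 0; tt$bio$twin_di[] <- 0
  tt$bio$bf_prob[] <- 0
  # one child then perfectly-protected limiting: full late window exposure
  tt$fp$dfs_w[] <- 1; tt$fp$dfs_kstar <- 1L
  tt$fp$metneed_b[] <- 50
  tt$fp$fail_annual[] <- 0
  h <- 0.01
  tt$comp$late_hazard[] <- h
  tl <- simulate_world(world, tt, seed = 14, years = 2000:2007,
                       n_agents = 4000)
  n_del <- attr(tl, "flows")[["deliveries"]]
  # only count deliveries whose full window closed within the run: rough
  # truncation is avoided by ignoring the last year of deliveries
  late <- sum(tl$deaths_cause[, , 8])
  p <- 1 - (1 - h)^11
  # deliveries in the final 12 cycles have open windows; bound both ways
  expect_gt(n_del, 800)
  expect_gt(late / n_del, p * 0.8 - 3 * sqrt(p * (1 - p) / n_del))
  expect_lt(late / n_del, p + 3 * sqrt(p * (1 - p) / n_del))
})

test_that("late hazard zero produces no late deaths", {
  g <- tiny_world()
  tt <- g$truth
  tt$comp$late_hazard[] <- 0
  tl <- simulate_world(g$world, tt, seed = 15, years = 1995:2000)
  expect_equal(sum(tl$deaths_cause[, , 8]), 0)
})

test_that("underreporting: reported deaths never exceed true deaths and
           survey capture dominates CRVS", {
  g <- tiny_world()
  tl <- simulate_world(g$world, g$truth, seed = 16)
  for (s in 1:2) {
    expect_true(all(tl$reported[, , , s] <= tl$deaths_cause + 1e-9))
  }
  # capture probability arrays: survey >= CRVS everywhere by construction
  P <- build_engine_params(g$world, g$truth)
  expect_true(all(P$capture[, , , 2] >= P$capture[, , , 1]))

  # degenerate captures: 1 reports everything, 0 nothing
  t1 <- g$truth
  t1$hs$capture_b[] <- 50
  t1$hs$capture_site_shift[] <- 0
  t1$hs$capture_slope[] <- 0
  t1$hs$survey_boost <- 0
  tl1 <- simulate_world(g$world, t1, seed = 17, years = 1995:2000)
  expect_equal(sum(abs(tl1$reported[, , , 1] - tl1$deaths_cause)), 0)

  t0 <- g$truth
  t0$hs$capture_b[] <- -50
  t0$hs$capture_site_shift[] <- 0
  t0$hs$capture_slope[] <- 0
  tl0 <- simulate_world(g$world, t0, seed = 18, years = 1995:2000)
  expect_equal(sum(tl0$reported), 0)
})

test_that("binomial capture: reported share matches the capture probability", {
  g <- solo_world()
  world <- no_entrants(flat_mortality(g$world, 0))
  tt <- home_delivery_only(no_interventions(no_recognition(fertile_base(g))))
  tt$comp$base[] <- 0
  tt$comp$base[, 3] <- 1
  tt$comp$sev_frac[] <- 1
  tt$comp$cfr_severe[] <- 0.5
  tt$comp$cfr_shift[] <- 0
  tt$hs$capture_b[] <- stats::qlogis(0.6)
  tt$hs$capture_site_shift[] <- 0
  tt$hs$capture_slope[] <- 0
  tt$hs$survey_boost <- 0
  tl <- simulate_world(world, tt, seed = 19, years = 2000:2003,
                       n_agents = 1500)
  deaths <- sum(tl$deaths_cause[, , 1])
  rep_ <- sum(tl$reported[, , 1, 1])
  expect_gt(deaths, 800)
  se <- sqrt(deaths * 0.6 * 0.4)
  expect_lt(abs(rep_ - 0.6 * deaths), 3 * se)
})

test_that("raising quality or availability never increases maternal deaths", {
  g <- tiny_world()
  lo <- g$truth
  hi <- g$truth
  hi$hs$quality_base[] <- pmin(hi$hs$quality_base + 0.3, 0.99)
  for (nm in names(hi$interv)) {
    hi$interv[[nm]]$avail_base <- pmin(hi$interv[[nm]]$avail_base + 0.3,
                                       0.99)
  }
  d <- function(tt, seed) {
    tl <- simulate_world(g$world, tt, seed = seed)
    sum(tl$deaths_cause[, , c(1:6)]) # direct causes respond to care
  }
  d_lo <- d(lo, 20); d_hi <- d(hi, 20) # common seed: paired comparison
  expect_lte(d_hi, d_lo + 3 * sqrt(d_lo + d_hi + 1))
})
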