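# Shared fixtures, all generated in code. Worlds are cached per session so
# test files can reuse them without re-drawing.

.world_cache <- new.env(parent = emptyenv())

cached_world <- function(key, ...) {
  if (is.null(.world_cache[[key]])) {
    .world_cache[[key]] <- generate_synthetic_world(...)
  }
  .world_cache[[key]]
}

tiny_world <- function() {
  cached_world("tiny", n_countries = 2, seed = 42, years = 1995:2004,
               report_from = 1998, n_agents = 150)
}

# one-country world for controlled engine experiments
solo_world <- function() {
  cached_world("solo", n_countries = 1, seed = 11, years = 2000:2009,
               report_from = 2002, n_agents = 400)
}

# ---- parameter-set surgery helpers ---------------------------------------

# switch off every source of pregnancy loss, complication and death
quiet_pset <- function(truth) {
  truth$comp$base[] <- 0
  truth$comp$late_hazard[] <- 0
  truth$bio$misc_base[] <- 0
  truth$bio$ect_base[] <- 0
  truth$bio$sb_base[] <- 0
  truth$fp$abortion_b[] <- -50
  truth$fp$abortion_slope[] <- 0
  truth
}

flat_mortality <- function(world, q) {
  world$lifetable[] <- q
  world
}

no_entrants <- function(world) {
  world$entry_schedule[] <- 0L
  world
}

no_contraception <- function(truth) {
  truth$fp$metneed_b[] <- -50
  truth$fp$metneed_slope[] <- 0
  truth
}

# constant fecundity at all reproductive ages, no twins, no breastfeeding
fixed_fecundity <- function(truth, f) {
  truth$bio$fec_band[] <- f
  truth$bio$twin_mono <- 0
  truth$bio$twin_di[] <- 0
  truth$bio$bf_prob[] <- 0
  truth
}

early_debut <- function(truth) {
  truth$fp$debut_median_m[] <- 121
  truth$fp$debut_logsd <- 1e-9
  truth
}

home_delivery_only <- function(truth) {
  truth$hs$site_base_logit[] <- rep(c(30, -30, -30, -30, -30),
                                    each = nrow(truth$hs$site_base_logit))
  truth$hs$sg_facility_shift[] <- 0
  truth$hs$site_trend_slope[] <- 0
  truth$hs$ecs_b[] <- -50
  truth
}

no_interventions <- function(truth) {
  for (nm in names(truth$interv)) truth$interv[[nm]]$avail_base <- rep(0, 5)
  truth
}

no_recognition <- function(truth) {
  truth$hs$recog_base <- rep(1e-12, 5)
  truth$hs$recog_sev_boost <- 0
  truth$hs$anc_any_b[] <- -50 # no ANC recognition boost either
  truth$hs$anc_any_slope[] <- 0
  truth
}

no_anc <- function(truth) {
  truth$hs$anc_any_b[] <- -50
  truth$hs$anc_any_slope[] <- 0
  truth
}

# tally environment suitable for driving advance_month() directly
empty_tally_env <- function(countries, years) {
  tl <- list2env(unclass(new_event_tally(countries, years)),
                 parent = emptyenv())
  tl$flows <- c(conceptions = 0, miscarriages = 0, ectopics = 0,
                abortions = 0, stillbirth_terminations = 0, deliveries = 0,
                pregnancies_interrupted = 0, births_f = 0, births_m = 0)
  tl$site_deliv <- numeric(5)
  tl$comp_count <- numeric(5)
  tl
}

# event-tally slice over the reporting years, summed over countries
tally_totals <- function(tl, world) {
  yi <- which(tl$years >= world$report_from)
  list(
    births = sum(tl$live_births[, yi]),
    maternal = sum(tl$deaths_cause[, yi, 1:7]),
    late = sum(tl$deaths_cause[, yi, 8]),
    by_cause = apply(tl$deaths_cause[, yi, , drop = FALSE], 3, sum)
  )
}

# hand-built tally for exact indicator arithmetic
manual_tally <- function(births, deaths_by_cause, preg_related = NULL,
                         all_1549 = NULL, py = 1e5) {
  tl <- new_event_tally("X", 2000L)
  tl$live_births[1, 1] <- births
  tl$deaths_cause[1, 1, ] <- deaths_by_cause
  md <- sum(deaths_by_cause[1:7])
  tl$preg_related[1, 1] <- if (is.null(preg_related)) md else preg_related
  tl$deaths_all_1549[1, 1] <- if (is.null(all_1549)) max(md, 1) else all_1549
  tl$py_age[1, 1, ] <- py / 35
  # spread maternal (non-late) deaths uniformly over ages
  tl$mat_deaths_age[1, 1, ] <- md / 35
  tl
}
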