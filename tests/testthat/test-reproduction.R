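# Conception, gestation, pregnancy loss, delivery timing, lactational
# amenorrhea, menopause and anemia.

# run one cycle of the engine on a purpose-built cohort and return the
# tally environment plus population
one_cycle <- function(world, truth, n, setup = identity, seed = 1,
                      month = 2) {
  P <- build_engine_params(world, truth)
  set.seed(seed)
  pop <- init_population(world, P, n)
  setup(pop)
  tl <- empty_tally_env(world$countries, world$years)
  advance_month(pop, P, tl, 1L, month)
  list(pop = pop, tl = tl, P = P)
}

test_that("conception probability composes fecundity, LAM and failure", {
  expect_equal(conception_prob(0.2, 1, FALSE, 0), 0.2)
  expect_equal(conception_prob(0.2, 0.2, FALSE, 0), 0.04)
  expect_lt(abs(conception_prob(0.2, 1, TRUE, annual_to_monthly(0.09)) -
                  0.007829), 1e-6)
  expect_equal(conception_prob(0, 1, FALSE, 0), 0)
})

test_that("monthly conception rate matches fecundity for unprotected women", {
  g <- solo_world()
  world <- no_entrants(flat_mortality(g$world, 0))
  truth <- early_debut(no_contraception(fixed_fecundity(quiet_pset(g$truth),
                                                        0.2)))
  n <- 3e4
  r <- one_cycle(world, truth, n, setup = function(pop) {
    pop$age[] <- 300L # 25-year-olds, sexually active, not postpartum
  })
  p_hat <- r$tl$flows[["conceptions"]] / n
  se <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs(p_hat - 0.2), 3 * se)
})

test_that("fecundity zero means no conception, ever", {
  g <- solo_world()
  truth <- no_contraception(fixed_fecundity(quiet_pset(g$truth), 0))
  tl <- simulate_world(flat_mortality(g$world, 0), truth, seed = 2)
  expect_equal(attr(tl, "flows")[["conceptions"]], 0)
  expect_equal(sum(tl$live_births), 0)
})

test_that("fetus counts and sexes follow twinning and the primary sex ratio", {
  g <- solo_world()
  truth <- quiet_pset(g$truth)
  truth$bio$twin_mono <- 0.01
  truth$bio$twin_di[] <- 0.02 # total twin probability 0.03 at every age
  P <- build_engine_params(g$world, truth)
  set.seed(4)
  n <- 4e4
  pop <- init_population(g$world, P, n)
  pop$age[] <- 300L
  pop$nect[] <- 0L
  maternalsim:::.start_pregnancy(pop, P, seq_len(n), 1L)
  twin_share <- mean(pop$nfet[!pop$ect] == 2L)
  se_t <- sqrt(0.03 * 0.97 / n)
  expect_lt(abs(twin_share - 0.03), 3 * se_t)
  # P(F) = 1 / (1 + 1.05) per fetus
  pF <- 1 / (1 + 1.05)
  nf <- sum(pop$nfet)
  se_f <- sqrt(pF * (1 - pF) / nf)
  expect_lt(abs(sum(pop$nfem) / nf - pF), 3 * se_f)
})

test_that("a prior ectopic multiplies the ectopic risk by the recurrence RR", {
  g <- solo_world()
  truth <- quiet_pset(g$truth)
  truth$bio$ect_base[] <- 0.01
  truth$bio$ect_rr_recur <- 3
  P <- build_engine_params(g$world, truth)
  set.seed(5)
  n <- 5e4
  pop <- init_population(g$world, P, n)
  pop$age[] <- 300L
  pop$nect[seq_len(n / 2)] <- 1L
  maternalsim:::.start_pregnancy(pop, P, seq_len(n), 1L)
  p1 <- mean(pop$ect[seq_len(n / 2)])        # with history
  p0 <- mean(pop$ect[(n / 2 + 1):n])         # naive
  se <- sqrt(0.03 * 0.97 / (n / 2) + 9 * 0.01 * 0.99 / (n / 2))
  expect_lt(abs(p1 - 3 * p0), 3 * se)
})

test_that("delivery month draws follow the fetal lifetable", {
  expect_true(all(schedule_delivery(100, c(0, 0, 1, 0)) == 9L))
  set.seed(6)
  n <- 1e5
  probs <- c(0.1, 0.1, 0.7, 0.1)
  d <- schedule_delivery(n, probs)
  for (i in 1:4) {
    se <- sqrt(probs[i] * (1 - probs[i]) / n)
    expect_lt(abs(mean(d == (6 + i)) - probs[i]), 3 * se)
  }
  expect_error(schedule_delivery(10, c(0.4, 0.3, 0.1, 0.1)), "sum to 1")
})

test_that("with all loss hazards zero every pregnancy delivers on schedule", {
  g <- solo_world()
  world <- no_entrants(flat_mortality(g$world, 0))
  truth <- early_debut(no_contraception(fixed_fecundity(quiet_pset(g$truth),
                                                        0.15)))
  tl <- simulate_world(world, truth, seed = 7)
  f <- attr(tl, "flows")
  expect_equal(f[["miscarriages"]], 0)
  expect_equal(f[["ectopics"]], 0)
  expect_equal(f[["stillbirth_terminations"]], 0)
  expect_gt(f[["deliveries"]], 0)
  expect_equal(f[["conceptions"]],
               f[["deliveries"]] + f[["abortions"]] +
                 attr(tl, "ongoing_pregnancies"))
})

test_that("certain miscarriage ends every pregnancy before delivery", {
  g <- solo_world()
  truth <- early_debut(no_contraception(fixed_fecundity(quiet_pset(g$truth),
                                                        0.15)))
  truth$bio$misc_base[] <- 1
  tl <- simulate_world(flat_mortality(g$world, 0), truth, seed = 8)
  f <- attr(tl, "flows")
  expect_gt(f[["conceptions"]], 0)
  expect_equal(f[["deliveries"]], 0)
  expect_equal(f[["miscarriages"]] + attr(tl, "ongoing_pregnancies"),
               f[["conceptions"]])
})

test_that("miscarriage history doubles the applied hazard", {
  g <- solo_world()
  world <- no_entrants(flat_mortality(g$world, 0))
  truth <- quiet_pset(g$truth)
  truth$bio$misc_base[] <- 0.05
  truth$bio$misc_rr_hist <- 2
  P <- build_engine_params(world, truth)
  n <- 4e4
  for (hist in c(0L, 1L)) {
    set.seed(9 + hist)
    pop <- init_population(world, P, n)
    pop$age[] <- 300L
    pop$preg[] <- TRUE
    pop$gest[] <- 1L
    pop$sched[] <- 9L
    pop$nfet[] <- 1L
    pop$nfem[] <- 0L
    pop$ect[] <- FALSE
    pop$abdec[] <- TRUE
    pop$nmisc[] <- hist
    tl <- empty_tally_env(world$countries, world$years)
    maternalsim:::.pregnancy_month(pop, P, tl, seq_len(n), 1L)
    p_hat <- tl$flows[["miscarriages"]] / n
    p_exp <- 0.05 * (1 + hist)
    se <- sqrt(p_exp * (1 - p_exp) / n)
    expect_lt(abs(p_hat - p_exp), 3 * se)
  }
})

test_that("lactational amenorrhea multiplies fecundity only through month 9", {
  g <- solo_world()
  world <- no_entrants(flat_mortality(g$world, 0))
  truth <- early_debut(no_contraception(quiet_pset(g$truth)))
  truth$bio$fec_band[] <- 0.2
  truth$bio$twin_mono <- 0; truth$bio$twin_di[] <- 0
  truth$bio$lam_excl_mult <- 0.2
  n <- 3e4
  nursing_setup <- function(pp) function(pop) {
    pop$age[] <- 300L
    pop$pp[] <- pp
    pop$bfr[] <- 20L
    pop$bfe[] <- TRUE
    pop$since_birth[] <- pp
    pop$living[] <- 1L
    pop$desired[] <- 5L
  }
  # exclusive breastfeeding at 3 months postpartum: p = 0.2 * 0.2
  r1 <- one_cycle(world, truth, n, nursing_setup(3L), seed = 10)
  p1 <- r1$tl$flows[["conceptions"]] / n
  se1 <- sqrt(0.04 * 0.96 / n)
  expect_lt(abs(p1 - 0.04), 3 * se1)
  # 10 months postpartum: the LAM effect has ceased despite breastfeeding
  r2 <- one_cycle(world, truth, n, nursing_setup(10L), seed = 11)
  p2 <- r2$tl$flows[["conceptions"]] / n
  se2 <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs(p2 - 0.2), 3 * se2)
})

test_that("menopause draws are truncated normal; anemia uses WHO cuts", {
  expect_true(all(draw_menopause(100, 600, 0) == 600L))
  set.seed(12)
  m <- draw_menopause(1e4, 600, 42)
  expect_true(all(m >= 480 & m <= 720))
  expect_error(draw_menopause(10, 600, -1), ">= 0")

  expect_true(is_anemic(10, pregnant = TRUE))
  expect_false(is_anemic(11.5, pregnant = TRUE))
  expect_true(is_anemic(11.5, pregnant = FALSE))
  # prevalence oracle: Hb ~ N(12, 1), pregnant cut 11 -> Phi(-1)
  set.seed(13)
  hb <- rnorm(1e5, 12, 1)
  prev <- mean(is_anemic(hb, pregnant = TRUE))
  p <- pnorm(-1)
  expect_lt(abs(prev - p), 3 * sqrt(p * (1 - p) / 1e5))
})

test_that("no conception occurs during pregnancy or after menopause", {
  g <- tiny_world()
  tl <- simulate_world(g$world, g$truth, seed = 14)
  # structural: conceptions equal pregnancy starts; a second conception
  # while pregnant would break the outcome partition checked here
  f <- attr(tl, "flows")
  outcomes <- sum(f[c("miscarriages", "ectopics", "abortions",
                      "stillbirth_terminations", "deliveries",
                      "pregnancies_interrupted")])
  expect_equal(f[["conceptions"]], outcomes + attr(tl, "ongoing_pregnancies"))

  # post-menopause: a cohort past its menopause age never conceives
  world <- no_entrants(flat_mortality(solo_world()$world, 0))
  truth <- early_debut(no_contraception(fixed_fecundity(
    quiet_pset(solo_world()$truth), 0.3)))
  r <- one_cycle(world, truth, 5000, setup = function(pop) {
    pop$age[] <- 640L
    pop$menop[] <- 600L
  })
  expect_equal(r$tl$flows[["conceptions"]], 0)
})

test_that("waiting time to conception is geometric in the fecundity", {
  g <- solo_world()
  world <- no_entrants(flat_mortality(g$world, 0))
  f <- 0.15
  truth <- early_debut(no_contraception(fixed_fecundity(quiet_pset(g$truth),
                                                        f)))
  P <- build_engine_params(world, truth)
  set.seed(15)
  n <- 2e4
  pop <- init_population(world, P, n)
  pop$age[] <- 276L
  pop$pp[] <- -1L
  tl <- empty_tally_env(world$countries, world$years)
  for (m in 1:8) advance_month(pop, P, tl, 1L, m + 1L)
  # within 8 cycles no woman can conceive twice (gestation is longer)
  p_hat <- tl$flows[["conceptions"]] / n
  p_exp <- 1 - (1 - f)^8
  se <- sqrt(p_exp * (1 - p_exp) / n)
  expect_lt(abs(p_hat - p_exp), 3 * se)
})
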