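# One-year aggregate transition frequencies are compared with their
# configured effective probabilities via exact binomial intervals; each
# experiment isolates a single chart by zeroing everything else.

test_that("behavior toggles recover their base rates with influence off", {
  n <- 10000
  net <- empty_network(n)
  cases <- list(
    list(tab = zero_transition_table(keep = "diet_to_healthy"),
         cohort = make_cohort(n, diet = "unhealthy"),
         changed = function(p) p$diet == "healthy", rate = 0.03),
    list(tab = zero_transition_table(keep = "activity_to_active"),
         cohort = make_cohort(n, activity = "inactive"),
         changed = function(p) p$activity == "active", rate = 0.049),
    list(tab = zero_transition_table(keep = "activity_to_inactive"),
         cohort = make_cohort(n, activity = "active"),
         changed = function(p) p$activity == "inactive", rate = 0.049)
  )
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    set.seed(1000 + i)
    out <- step_year(cs$cohort, net, cs$tab, influence_off())
    expect_binomial_rate(sum(cs$changed(out)), n, cs$rate)
  }
})

test_that("age-banded smoking rates apply by band", {
  n <- 8000
  tab <- zero_transition_table(keep = "smoking_start")
  tab$smoking_start$p <- c(0.2, 0.05, 0)
  young <- make_cohort(n, age = 25, smoking = "not_smoking")
  old <- make_cohort(n, age = 70, smoking = "not_smoking")
  set.seed(2)
  out_y <- step_year(young, empty_network(n), tab, influence_off())
  out_o <- step_year(old, empty_network(n), tab, influence_off())
  expect_binomial_rate(sum(out_y$smoking == "smoking"), n, 0.2)
  expect_equal(sum(out_o$smoking == "smoking"), 0)
})

test_that("social influence rescales the toggle probability", {
  # alternating ring (k = 2): every inactive agent has two active
  # neighbors, laplace F = (2+1)/(0+1) = 3, capped at 2 -> effective
  # activation probability 0.049 * 2 = 0.098
  n <- 3000
  net <- build_ring_lattice(n, 2)
  pop <- make_cohort(n, activity = "inactive")
  pop$activity[seq(1, n, by = 2)] <- "active"
  # alternating ring: every inactive agent has all-active neighbors
  tab <- zero_transition_table(keep = "activity_to_active")
  cfg <- influence_config(f_cap = 2)
  set.seed(3)
  out <- step_behaviors(pop, list(
    smoking = count_signals(pop$smoking == "not_smoking", rep(TRUE, n), net),
    diet = count_signals(pop$diet == "healthy", rep(TRUE, n), net),
    activity = count_signals(pop$activity == "active", rep(TRUE, n), net)
  ), tab, cfg)
  was_inactive <- pop$activity == "inactive"
  expect_binomial_rate(sum(out$activity[was_inactive] == "active"),
                       sum(was_inactive), 0.098)
})

test_that("weight transitions multiply behavioral risk factors", {
  n <- 10000
  tab <- zero_transition_table(keep = c("weight_gain_base"))
  tab$weight_gain_base <- 0.05
  tab$weight_gain_mult_unhealthy_diet <- 1.5
  tab$weight_gain_mult_inactive <- 1.5
  risky <- make_cohort(n, diet = "unhealthy", activity = "inactive")
  set.seed(4)
  out <- step_weight(risky, tab)
  expect_binomial_rate(sum(out$weight == "overweight"), n, 0.1125)

  safe <- make_cohort(n, diet = "healthy", activity = "active")
  set.seed(5)
  out <- step_weight(safe, tab)
  expect_binomial_rate(sum(out$weight == "overweight"), n, 0.05)

  tab$weight_gain_base <- 0
  out <- step_weight(risky, tab)
  expect_true(all(out$weight == "normal"))
})

test_that("comorbidity onset multiplies age and weight modifiers", {
  n <- 10000
  tab <- zero_transition_table(keep = "htn_base")
  tab$htn_base <- 0.02
  tab$htn_age_mult$mult <- c(1, 2, 2)
  tab$htn_overweight_mult <- 1.5
  cohort <- make_cohort(n, age = 50, weight = "overweight")
  set.seed(6)
  out <- step_comorbidity(cohort, tab)
  expect_binomial_rate(sum(out$hypertension == "yes"), n, 0.06)

  # remission off: hypertension never reverses
  sick <- make_cohort(n, hypertension = "yes")
  out <- step_comorbidity(sick, zero_transition_table())
  expect_true(all(out$hypertension == "yes"))
})

test_that("glycemic chart converts, reverses, and absorbs correctly", {
  n <- 10000
  tab <- zero_transition_table(keep = "dm_pre_to_dm_base")
  tab$dm_pre_to_dm_base <- 0.1
  tab$dm_age_mult$mult <- c(1, 1, 1)
  tab$dm_overweight_mult <- 1
  pre <- make_cohort(n, glycemic = "prediabetes")
  set.seed(7)
  out <- step_glycemic(pre, tab)
  expect_binomial_rate(sum(out$glycemic == "diabetes"), n, 0.1)

  dm <- make_cohort(100, glycemic = "diabetes")
  tab2 <- transition_table()  # full default rates
  set.seed(8)
  out <- step_glycemic(dm, tab2)
  expect_true(all(out$glycemic == "diabetes"))  # absorbing
})

test_that("complication charts follow their gating rules", {
  n <- 10000
  set.seed(9)
  out <- step_complications(make_cohort(n), zero_transition_table(
    keep = c("neph_onset")))
  expect_binomial_rate(sum(out$nephropathy == "yes"), n, 0.01)

  # retinopathy never initiates in non-diabetics
  tab <- zero_transition_table(keep = c("retina_onset", "retina_to_blind"))
  tab$retina_onset <- 1
  tab$retina_to_blind <- 1
  set.seed(10)
  out <- step_complications(make_cohort(500, glycemic = "none"), tab)
  expect_true(all(out$retina == "normal"))
  out <- step_complications(make_cohort(500, glycemic = "diabetes"), tab)
  expect_true(all(out$retina == "diabetic_retina"))  # one step per year

  # every CVD event is fatal when fatality = 1
  tab <- zero_transition_table(keep = "cvd_event")
  tab$cvd_event$p <- 0.5
  tab$cvd_fatality <- 1
  set.seed(11)
  out <- step_complications(make_cohort(2000), tab)
  had_event <- out$cvd != "none"
  expect_true(all(out$cvd[had_event] == "death"))
})

test_that("a zero-rate year only increments age", {
  set.seed(12)
  pop <- generate_population(population_spec(n = 300))
  out <- step_year(pop, empty_network(300), zero_transition_table(),
                   influence_off())
  aged <- pop
  aged$age <- aged$age + 1L
  expect_identical(as.data.frame(out), as.data.frame(aged))
})

test_that("annual stepping is deterministic under a fixed seed", {
  spec <- population_spec(n = 400)
  run_once <- function() {
    set.seed(99)
    pop <- generate_population(spec)
    net <- build_small_world(400, 6, 0.1)
    for (y in 1:3) pop <- step_year(pop, net, transition_table())
    pop
  }
  expect_identical(run_once(), run_once())
})

test_that("absorbing states are never left over a long horizon", {
  set.seed(13)
  spec <- population_spec(n = 1000)
  pop <- generate_population(spec)
  net <- build_small_world(1000, 6, 0.1)
  tab <- transition_table()
  dead <- rep(FALSE, 1000); blind <- rep(FALSE, 1000); dm <- rep(FALSE, 1000)
  ages <- pop$age
  for (y in 1:15) {
    pop <- step_year(pop, net, tab)
    now_dead <- pop$cvd == "death"
    now_blind <- pop$retina == "blindness"
    now_dm <- pop$glycemic == "diabetes"
    expect_true(all(now_dead[dead]))
    expect_true(all(now_blind[blind]))
    expect_true(all(now_dm[dm]))
    # dead agents do not age; survivors age exactly 1 per year
    expect_true(all(pop$age[!now_dead] == ages[!now_dead] + 1L))
    ages <- pop$age
    dead <- now_dead; blind <- now_blind; dm <- now_dm
  }
  # living count non-increasing by construction (deaths only)
  expect_lte(sum(pop$cvd != "death"), 1000)
})

test_that("retinopathy only ever appears in diabetic agents", {
  set.seed(14)
  pop <- generate_population(population_spec(n = 2000))
  net <- build_small_world(2000, 6, 0.1)
  tab <- transition_table(retina_onset = 0.2)
  for (y in 1:5) {
    pop <- step_year(pop, net, tab)
    affected <- pop$retina != "normal"
    expect_true(all(pop$glycemic[affected] == "diabetes"))
  }
})

test_that("symmetric diet rates converge to the 50/50 stationary split", {
  n <- 10000
  tab <- zero_transition_table(keep = c("diet_to_healthy",
                                        "diet_to_unhealthy"))
  pop <- make_cohort(n, diet = "unhealthy")
  net <- empty_network(n)
  set.seed(15)
  for (y in 1:200) pop <- step_year(pop, net, tab, influence_off())
  # stationary distribution p/(p+q) = 0.5; binomial 3-SE band
  se <- sqrt(0.25 / n)
  expect_lt(abs(mean(pop$diet == "healthy") - 0.5), 3 * se)
})
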