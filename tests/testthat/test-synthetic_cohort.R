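test_that("invalid configuration names the offending field", {
  expect_error(cohort_config(n_participants = 1), "n_participants")
  expect_error(cohort_config(gender_ratio = 1.5), "gender_ratio")
  expect_error(cohort_config(income_missing_rate = -0.1),
               "income_missing_rate")
  expect_error(cohort_config(choice_temperature = 0), "choice_temperature")
})

test_that("null configuration gives equal gender means", {
  cfg <- cohort_config(n_participants = 400, memory_gender_gap = 0,
                       effect_gender_memory_on_lnk = 0)
  cohort <- generate_cohort(cfg, seed = 42)
  by_gender <- cohort |>
    dplyr::group_by(gender) |>
    dplyr::summarise(dplyr::across(c(fnpa_pf, igd_c1, igd_c2), mean))
  # Monte-Carlo error at n ~ 200/group: 3 * sd/sqrt(n) ~ 0.05
  for (v in c("fnpa_pf", "igd_c1", "igd_c2")) {
    expect_lt(abs(diff(by_gender[[v]])), 0.06)
  }
})

test_that("default memory means emulate the gender-structured targets", {
  cohort <- generate_cohort(cohort_config(n_participants = 58), seed = 7)
  m <- mean(cohort$fnpa_pf[cohort$gender == "male"])
  f <- mean(cohort$fnpa_pf[cohort$gender == "female"])
  # within 2 SE of the configured group means (SE ~ 0.21/sqrt(28) ~ 0.04)
  expect_lt(abs(m - 0.33), 2 * 0.21 / sqrt(28))
  expect_lt(abs(f - 0.57), 2 * 0.21 / sqrt(30))
  expect_gt(f, m)
  expect_equal(sum(cohort$gender == "female"), 30)
})

test_that("score ranges and truth bounds hold for every seed", {
  for (seed in 1:5) {
    cohort <- generate_cohort(cohort_config(n_participants = 40), seed = seed)
    expect_true(all(cohort$fnpa_pf >= -1 & cohort$fnpa_pf <= 1))
    expect_true(all(cohort$igd_c1 >= 0 & cohort$igd_c1 <= 2))
    expect_true(all(cohort$igd_c2 >= 0 & cohort$igd_c2 <= 2))
    expect_true(all(cohort$true_k >= 0))
    expect_true(all(cohort$true_beta >= 0 & cohort$true_beta <= 1))
    expect_true(all(cohort$true_delta >= 0 & cohort$true_delta <= 1))
    expect_true(all(cohort$age >= 60 & cohort$age <= 89))
  }
})

test_that("income missingness is binomial at the configured rate", {
  counts <- vapply(1:30, function(s) {
    cohort <- generate_cohort(
      cohort_config(n_participants = 60, income_missing_rate = 0.1),
      seed = s
    )
    sum(is.na(cohort$income))
  }, numeric(1))
  expect_equal(mean(counts), 6, tolerance = 0.25)
  expect_gt(stats::sd(counts), 0)   # random, not a fixed quota
})

test_that("degenerate responders follow the subjective-value ordering", {
  design <- build_choice_design("p1", 1)
  # beta = delta = 1, infinite temperature: later iff strictly larger amount
  truth <- list(true_beta = 1, true_delta = 1, choice_temperature = Inf)
  tr <- simulate_choices(truth, design, seed = 1)
  strict <- tr$later_amount > tr$sooner_amount
  expect_true(all(tr$choice[strict] == "later"))
  # 20-vs-20 ties: close to fair coin across seeds
  tie_choices <- unlist(lapply(1:40, function(s) {
    simulate_choices(truth, design, seed = s)$choice[design$sooner_amount == 20]
  }))
  expect_gt(mean(tie_choices == "sooner"), 0.35)
  expect_lt(mean(tie_choices == "sooner"), 0.65)
})

test_that("closed-form threshold governs deterministic beta-delta choice", {
  design <- build_choice_design("p1", 2)
  b1 <- design[design$block == 1, ]   # T = 3, sooner tomorrow
  truth <- list(true_beta = 0.5, true_delta = 0.98,
                choice_temperature = Inf)
  tr <- simulate_choices(truth, b1, seed = 1)
  thr <- 20 * 0.5 * 0.98^3   # sooner value above this dominates
  expect_true(all(tr$choice[tr$sooner_amount < thr] == "later"))
  expect_true(all(tr$choice[tr$sooner_amount > thr] == "sooner"))
})

test_that("zero temperature yields pure-noise choices", {
  design <- build_choice_design("p1", 3)
  truth <- list(true_beta = 0.6, true_delta = 0.9, choice_temperature = 0)
  props <- vapply(1:30, function(s) {
    mean(simulate_choices(truth, design, seed = s)$choice == "later")
  }, numeric(1))
  expect_equal(mean(props), 0.5, tolerance = 0.03)
})

test_that("malformed designs are rejected", {
  design <- build_choice_design("p1", 1)
  design$sooner_amount[3] <- NA
  truth <- list(true_beta = 1, true_delta = 1, choice_temperature = 1)
  expect_error(simulate_choices(truth, design, 1), "malformed")
})

test_that("cohort simulation is reproducible and prefix-stable", {
  cfg <- cohort_config(n_participants = 6)
  cohort <- generate_cohort(cfg, seed = 3)
  t1 <- simulate_cohort_choices(cohort, seed = 9)
  t2 <- simulate_cohort_choices(cohort, seed = 9)
  expect_identical(t1, t2)
  # adding participants leaves earlier participants' trials unchanged
  cfg2 <- cohort_config(n_participants = 8)
  cohort2 <- generate_cohort(cfg2, seed = 3)
  cohort2[1:6, ] <- cohort   # same truths for the shared prefix
  t3 <- simulate_cohort_choices(cohort2, seed = 9)
  expect_identical(
    dplyr::filter(t3, participant_id %in% cohort$participant_id),
    t1
  )
})
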