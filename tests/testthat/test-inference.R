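make_bivariate <- function(n, rho, seed) {
  withr::with_seed(seed, {
    iq <- stats::rnorm(n)
    income <- rho * iq + sqrt(1 - rho^2) * stats::rnorm(n)
  })
  tibble::tibble(participant_id = as.character(seq_len(n)),
                 iq = iq, income = income)
}

test_that("EM imputation is the identity on complete data", {
  tab <- make_bivariate(50, 0.5, seed = 1)
  expect_identical(em_impute(tab), tab)
})

test_that("EM imputation converges to the conditional mean", {
  tab <- make_bivariate(400, 0.6, seed = 2)
  truth <- tab$income[7]
  tab$income[7] <- NA
  # monotone missingness in one column: the ML fixed point is regression
  # imputation from the complete cases
  cc <- tab[-7, ]
  oracle <- unname(stats::coef(stats::lm(income ~ iq, data = cc)) %*%
                     c(1, tab$iq[7]))
  imputed <- em_impute(tab, columns = c("iq", "income"))$income[7]
  expect_equal(imputed, drop(oracle), tolerance = 1e-3)
  expect_false(isTRUE(all.equal(imputed, truth)))   # estimate, not a lookup
  # observed entries untouched
  expect_identical(em_impute(tab, columns = c("iq", "income"))$income[-7],
                   tab$income[-7])
})

test_that("EM imputation preserves the column mean under MCAR", {
  tab <- make_bivariate(300, 0.5, seed = 3)
  withr::with_seed(4, {
    tab$income[stats::runif(300) < 0.1] <- NA
  })
  filled <- em_impute(tab, columns = c("iq", "income"))
  expect_false(anyNA(filled$income))
  expect_lt(abs(mean(filled$income) - 0), 2 / sqrt(300))
  tab$income <- NA_real_
  expect_error(em_impute(tab, columns = c("iq", "income")), "unimputable")
})

analysis_fixture <- function(n = 58, seed = 10, effect = 0, noise = 1) {
  cohort <- generate_cohort(
    cohort_config(n_participants = n, income_missing_rate = 0),
    seed = seed
  )
  gender01 <- as.numeric(cohort$gender == "female")
  withr::with_seed(seed + 1, {
    cohort$outcome <- effect * gender01 *
      (cohort$igd_c2 - mean(cohort$igd_c2)) + stats::rnorm(n, 0, noise)
  })
  cohort
}

test_that("standardized betas equal the normal-equations solution", {
  tab <- analysis_fixture()
  h <- fit_model_hierarchy(tab, "outcome")
  for (i in 1:3) {
    f <- h$models[[i]]
    x <- h$data[attr(stats::terms(f), "term.labels")]
    oracle <- ols_normal_equations(x, h$data$y)
    expect_equal(unname(stats::coef(f)), unname(oracle), tolerance = 1e-8)
  }
})

test_that("R-squared is non-decreasing across the hierarchy", {
  for (seed in c(20, 21)) {
    h <- fit_model_hierarchy(analysis_fixture(seed = seed), "outcome")
    g <- glance(h)
    expect_true(all(diff(g$r.squared) >= -1e-12))
    expect_true(all(g$adj.r.squared <= g$r.squared))
  }
})

test_that("an injected interaction is detected with high power", {
  hits <- vapply(1:40, function(s) {
    tab <- analysis_fixture(seed = 100 + s, effect = 0.8, noise = 0.15)
    h <- fit_model_hierarchy(tab, "outcome")
    co <- dplyr::filter(tidy(h), model == 3, term == "gender_x_igd_c2")
    co$p.value < 0.05 && co$estimate > 0
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("the increment F-test matches the residual-sum form", {
  tab <- analysis_fixture(seed = 30)
  h <- fit_model_hierarchy(tab, "outcome")
  g <- glance(h)
  a <- stats::anova(h$models[[2]], h$models[[3]])
  expect_equal(g$delta_r2_f[3], a$F[2], tolerance = 1e-8)
  expect_equal(g$delta_r2_p[3], a$`Pr(>F)`[2], tolerance = 1e-8)
  # the study-sized design: 3 added interactions at n = 58, 10 predictors
  expect_equal(g$delta_r2_df1[3], 3)
  expect_equal(g$delta_r2_df2[3], 58 - 10 - 1)
  # no improvement
  none <- delta_r2_f_test(0.3, 0.3, n = 58, p_full = 10, q = 3)
  expect_equal(none$statistic, 0)
  expect_equal(none$p.value, 1)
  expect_error(delta_r2_f_test(0.2, 0.4, 58, 10, 3), "nested")
})

test_that("group comparison selects and applies the right test", {
  # exchangeable groups: null-centered statistic
  withr::with_seed(40, v <- stats::rnorm(30))
  tab <- tibble::tibble(gender = rep(c("male", "female"), each = 30),
                        x = c(v, v))
  res <- compare_groups(tab, "x")
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p.value, 1)

  # a 1-SD mean shift at n = 28/30 is detected almost always
  detected <- vapply(1:60, function(s) {
    withr::with_seed(s, {
      tab <- tibble::tibble(
        gender = rep(c("male", "female"), c(28, 30)),
        x = c(stats::rnorm(28, 0), stats::rnorm(30, 1))
      )
    })
    r <- compare_groups(tab, "x")
    c(r$p.value < 0.05, r$test == "t")
  }, logical(2))
  expect_gt(mean(detected[1, ]), 0.9)
  expect_gt(mean(detected[2, ]), 0.7)

  # heavy skew routes to Mann-Whitney
  mw <- vapply(1:20, function(s) {
    withr::with_seed(200 + s, {
      tab <- tibble::tibble(
        gender = rep(c("male", "female"), each = 30),
        x = stats::rlnorm(60, 0, 1.5)
      )
    })
    compare_groups(tab, "x")$test == "mann-whitney"
  }, logical(1))
  expect_gt(mean(mw), 0.8)

  tab$x <- 1
  expect_error(compare_groups(tab, "x"), "constant")
})

test_that("Holm decisions match the literal step-down procedure", {
  withr::with_seed(50, {
    for (i in 1:200) {
      m <- sample(2:8, 1)
      p <- stats::runif(m)^sample(1:3, 1)
      expect_identical(holm_reject(p), holm_stepdown(p))
    }
  })
})

test_that("a smallest family p-value above alpha/3 is not significant", {
  expect_identical(holm_reject(c(0.018, 0.5, 0.7)), rep(FALSE, 3))
  expect_identical(holm_reject(c(0.016, 0.5, 0.7)),
                   c(TRUE, FALSE, FALSE))
})

test_that("correlation families are corrected within covariate", {
  tab <- analysis_fixture(seed = 60)
  res <- memory_covariate_correlations(tab)
  expect_equal(nrow(res), 9)
  for (cv in unique(res$covariate)) {
    fam <- res[res$covariate == cv, ]
    expect_equal(fam$p.holm, stats::p.adjust(fam$p.value, "holm"))
    expect_identical(fam$significant, holm_stepdown(fam$p.value))
  }
  # income is log-normal in the generator, so its family uses Spearman
  expect_true(all(res$method[res$covariate == "income"] == "spearman"))
})

test_that("median splits summarize gender-by-memory cells", {
  tab <- analysis_fixture(seed = 70)
  tab$flat <- 1.5
  s <- median_split_summary(tab, "igd_c2", "flat")
  expect_true(all(s$mean == 1.5))
  expect_true(all(s$se == 0))

  med <- stats::median(tab$igd_c2)
  tab$step <- ifelse(tab$igd_c2 > med, 1, -1)
  s2 <- median_split_summary(tab, "igd_c2", "step")
  expect_equal(s2$mean[s2$split == "high"], c(1, 1))
  expect_equal(s2$mean[s2$split == "low"], c(-1, -1))

  # an injected positive gender-by-memory slope on ln k reverses the
  # high/low ordering between genders
  cfg <- cohort_config(n_participants = 200, lnk_sd = 0.2,
                       effect_gender_memory_on_lnk = 4)
  cohort <- generate_cohort(cfg, seed = 71)
  s3 <- median_split_summary(cohort, "igd_c2", "true_lnk")
  male_hi <- s3$mean[s3$gender == "male" & s3$split == "high"]
  male_lo <- s3$mean[s3$gender == "male" & s3$split == "low"]
  fem_hi <- s3$mean[s3$gender == "female" & s3$split == "high"]
  fem_lo <- s3$mean[s3$gender == "female" & s3$split == "low"]
  expect_lt(male_hi, male_lo)
  expect_gt(fem_hi, fem_lo)
})
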