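#' Expectation-maximization imputation of missing covariates
#'
#' Fills missing entries of the numeric analysis columns under a joint
#' multivariate-normal model. Missing entries are initialized at the
#' observed column means; the E-step replaces them with their conditional
#' expectations given the observed entries of the same row, the M-step
#' re-estimates the mean vector and covariance (including the conditional
#' covariance of the imputed entries), and the cycle repeats until the
#' largest change in any imputed value falls below `tol` or `max_iter`
#' iterations. Observed values are never altered.
#'
#' @param table Per-participant tibble.
#' @param columns Numeric columns forming the joint model; defaults to the
#'   analysis covariates and memory scores present in `table`.
#' @param tol Convergence tolerance on imputed values.
#' @param max_iter Iteration cap.
#' @return `table` with missing entries of `columns` imputed.
#' @export
em_impute <- function(table,
                      columns = intersect(
                        c("age", "iq", "income",
                          "fnpa_pf", "igd_c1", "igd_c2"),
                        names(table)),
                      tol = 1e-6, max_iter = 200) {
  x <- as.matrix(table[columns])
  storage.mode(x) <- "double"
  miss <- is.na(x)
  if (!any(miss)) return(table)
  if (any(colSums(!miss) == 0)) {
    stop("unimputable input: a column is entirely missing", call. = FALSE)
  }

  n <- nrow(x)
  p <- ncol(x)
  mu <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(p)) x[miss[, j], j] <- mu[j]
  sigma <- crossprod(sweep(x, 2, mu)) / n

  for (iter in seq_len(max_iter)) {
    cond_cov <- matrix(0, p, p)
    x_new <- x
    for (i in which(rowSums(miss) > 0)) {
      m <- miss[i, ]
      o <- !m
      w <- sigma[m, o, drop = FALSE] %*% solve(sigma[o, o, drop = FALSE])
      x_new[i, m] <- mu[m] + w %*% (x[i, o] - mu[o])
      cond_cov[m, m] <- cond_cov[m, m] +
        sigma[m, m, drop = FALSE] - w %*% sigma[o, m, drop = FALSE]
    }
    delta <- max(abs(x_new[miss] - x[miss]))
    x <- x_new
    mu <- colMeans(x)
    sigma <- (crossprod(sweep(x, 2, mu)) + cond_cov) / n
    if (delta < tol) break
  }
  for (j in seq_len(p)) table[[columns[j]]][miss[, j]] <- x[miss[, j], j]
  table
}

#' Hierarchical regression of a discounting outcome
#'
#' Fits the three-step OLS hierarchy relating a discounting outcome to
#' memory, demographics, and gender-by-memory interactions:
#' model 1 regresses the outcome on the three memory scores (FNPA-PF,
#' IGD-C1, IGD-C2); model 2 adds gender, age, income and IQ; model 3 adds
#' the three gender-by-memory interactions, built by multiplying the
#' mean-centered memory scores with the gender indicator (female = 1,
#' male = 0). All variables — outcome, predictors, and the interaction
#' products — are z-scored before fitting, so coefficients are standardized
#' betas.
#'
#' @param table Complete (post-imputation) analysis tibble with columns
#'   `gender`, `age`, `iq`, `income`, `fnpa_pf`, `igd_c1`, `igd_c2` and the
#'   outcome.
#' @param outcome Name of the outcome column (e.g. `"ln_k"`, `"beta"`,
#'   `"delta"`, `"n_imp"`).
#' @return An object of class `dd_hierarchy`; see [tidy.dd_hierarchy()] and
#'   [glance.dd_hierarchy()].
#' @export
fit_model_hierarchy <- function(table, outcome) {
  stopifnot(outcome %in% names(table))
  if (anyNA(table[c("gender", "age", "iq", "income",
                    "fnpa_pf", "igd_c1", "igd_c2", outcome)])) {
    stop("analysis table must be complete; run em_impute() first",
         call. = FALSE)
  }
  n <- nrow(table)
  gender01 <- as.numeric(table$gender == "female")
  zs <- function(v) {
    s <- stats::sd(v)
    if (s == 0) stop("collinear or constant input column", call. = FALSE)
    (v - mean(v)) / s
  }
  d <- tibble::tibble(
    y = zs(table[[outcome]]),
    fnpa_pf = zs(table$fnpa_pf),
    igd_c1 = zs(table$igd_c1),
    igd_c2 = zs(table$igd_c2),
    gender = zs(gender01),
    age = zs(table$age),
    income = zs(table$income),
    iq = zs(table$iq),
    gender_x_fnpa_pf = zs(gender01 * (table$fnpa_pf - mean(table$fnpa_pf))),
    gender_x_igd_c1 = zs(gender01 * (table$igd_c1 - mean(table$igd_c1))),
    gender_x_igd_c2 = zs(gender01 * (table$igd_c2 - mean(table$igd_c2)))
  )
  f1 <- stats::lm(y ~ fnpa_pf + igd_c1 + igd_c2, data = d)
  f2 <- stats::update(f1, . ~ . + gender + age + income + iq)
  f3 <- stats::update(f2, . ~ . + gender_x_fnpa_pf + gender_x_igd_c1 +
                        gender_x_igd_c2)
  if (any(vapply(list(f1, f2, f3),
                 function(f) anyNA(stats::coef(f)), logical(1)))) {
    stop("collinear input: rank-deficient model matrix", call. = FALSE)
  }
  structure(
    list(models = list(f1, f2, f3), outcome = outcome, n = n, data = d),
    class = "dd_hierarchy"
  )
}

#' @export
print.dd_hierarchy <- function(x, ...) {
  cat("Hierarchical OLS for outcome `", x$outcome, "` (n = ", x$n, ")\n",
      sep = "")
  print(glance(x), ...)
  invisible(x)
}

#' Tidy a regression hierarchy
#'
#' @param x A `dd_hierarchy` from [fit_model_hierarchy()].
#' @param ... Unused.
#' @return A tibble with one row per model term: `model` (1-3), `term`,
#'   `estimate` (standardized beta), `std.error`, `statistic`, `p.value`.
#' @method tidy dd_hierarchy
#' @export
tidy.dd_hierarchy <- function(x, ...) {
  purrr::imap_dfr(x$models, function(f, i) {
    s <- summary(f)$coefficients
    tibble::tibble(
      model = i,
      term = rownames(s),
      estimate = s[, 1],
      std.error = s[, 2],
      statistic = s[, 3],
      p.value = s[, 4]
    )
  })
}

#' Model-level summary of a regression hierarchy
#'
#' @param x A `dd_hierarchy` from [fit_model_hierarchy()].
#' @param ... Unused.
#' @return A tibble with one row per model: F statistic and degrees of
#'   freedom, `r.squared`, `adj.r.squared`, `p.value`, and (for models 2
#'   and 3) the F-test of the R-squared increment over the previous model.
#' @method glance dd_hierarchy
#' @export
glance.dd_hierarchy <- function(x, ...) {
  base <- purrr::imap_dfr(x$models, function(f, i) {
    s <- summary(f)
    tibble::tibble(
      model = i,
      statistic = s$fstatistic[1],
      df1 = s$fstatistic[2],
      df2 = s$fstatistic[3],
      r.squared = s$r.squared,
      adj.r.squared = s$adj.r.squared,
      p.value = stats::pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
                          lower.tail = FALSE)
    )
  })
  inc <- purrr::map_dfr(2:3, function(i) {
    full <- summary(x$models[[i]])
    red <- summary(x$models[[i - 1]])
    p_full <- length(stats::coef(x$models[[i]])) - 1
    q <- p_full - (length(stats::coef(x$models[[i - 1]])) - 1)
    dr <- delta_r2_f_test(full$r.squared, red$r.squared, x$n, p_full, q)
    dplyr::mutate(dr, model = i)
  })
  dplyr::left_join(base, dplyr::rename(inc, delta_r2_f = "statistic",
                                       delta_r2_df1 = "df1",
                                       delta_r2_df2 = "df2",
                                       delta_r2_p = "p.value"),
                   by = "model")
}

#' F-test for an R-squared increment between nested models
#'
#' `F = ((R2_full - R2_reduced) / q) / ((1 - R2_full) / (n - p_full - 1))`
#' with `q` added terms, referred to an F distribution on
#' `(q, n - p_full - 1)` degrees of freedom.
#'
#' @param r2_full,r2_reduced R-squared of the full and reduced model.
#' @param n Sample size.
#' @param p_full Number of predictors in the full model (excluding the
#'   intercept).
#' @param q Number of added predictors.
#' @return A tibble with `statistic`, `df1`, `df2`, `p.value`.
#' @examples
#' delta_r2_f_test(0.579, 0.196, n = 58, p_full = 10, q = 3)
#' @export
delta_r2_f_test <- function(r2_full, r2_reduced, n, p_full, q) {
  if (q <= 0 || r2_full < r2_reduced - 1e-12) {
    stop("invalid comparison: models must be nested", call. = FALSE)
  }
  df2 <- n - p_full - 1
  f <- ((r2_full - r2_reduced) / q) / ((1 - r2_full) / df2)
  tibble::tibble(
    statistic = f, df1 = q, df2 = df2,
    p.value = stats::pf(f, q, df2, lower.tail = FALSE)
  )
}

#' Compare a variable between gender groups
#'
#' Shapiro-Wilk tests (alpha = 0.05) within each gender decide the test:
#' both groups compatible with normality gives a pooled-variance two-sample
#' t-test, otherwise a Mann-Whitney U (Wilcoxon rank-sum) test.
#'
#' @param table Analysis tibble with a `gender` column.
#' @param variable Name of the numeric column to compare.
#' @return One-row tibble: `variable`, `test` ("t" or "mann-whitney"),
#'   `statistic`, `p.value`, group means, and group sizes.
#' @export
compare_groups <- function(table, variable) {
  x <- table[[variable]][table$gender == "male"]
  y <- table[[variable]][table$gender == "female"]
  if (!length(x) || !length(y)) {
    stop("both gender groups must be nonempty", call. = FALSE)
  }
  if (stats::sd(c(x, y)) == 0) {
    stop("degenerate input: `", variable, "` is constant", call. = FALSE)
  }
  normal <- function(v) {
    length(v) >= 3 && stats::sd(v) > 0 && stats::shapiro.test(v)$p.value > 0.05
  }
  if (normal(x) && normal(y)) {
    ht <- stats::t.test(x, y, var.equal = TRUE)
    test <- "t"
  } else {
    ht <- stats::wilcox.test(x, y, exact = FALSE)
    test <- "mann-whitney"
  }
  tibble::tibble(
    variable = variable, test = test,
    statistic = unname(ht$statistic), p.value = ht$p.value,
    mean_male = mean(x), mean_female = mean(y),
    n_male = length(x), n_female = length(y)
  )
}

#' Correlations of memory scores with covariates, Holm-corrected
#'
#' For each covariate (age, IQ, income) and each memory score, computes
#' Pearson's r when both variables pass Shapiro-Wilk normality (alpha =
#' 0.05) and Spearman's rho otherwise, with two-tailed p-values.
#' Holm-Bonferroni correction is applied within each covariate's family of
#' three tests.
#'
#' @param table Complete analysis tibble.
#' @param covariates Covariate columns (default age, IQ, income).
#' @param scores Memory-score columns.
#' @param alpha Familywise significance level.
#' @return A tibble with one row per covariate-score pair: `method`,
#'   `estimate`, `p.value`, `p.holm`, `significant`.
#' @export
memory_covariate_correlations <- function(table,
                                          covariates = c("age", "iq",
                                                         "income"),
                                          scores = c("fnpa_pf", "igd_c1",
                                                     "igd_c2"),
                                          alpha = 0.05) {
  normal <- function(v) stats::shapiro.test(v)$p.value > 0.05
  purrr::map_dfr(covariates, function(cv) {
    fam <- purrr::map_dfr(scores, function(sc) {
      x <- table[[cv]]
      y <- table[[sc]]
      method <- if (normal(x) && normal(y)) "pearson" else "spearman"
      ct <- suppressWarnings(
        stats::cor.test(x, y, method = method, alternative = "two.sided",
                        exact = FALSE)
      )
      tibble::tibble(covariate = cv, score = sc, method = method,
                     estimate = unname(ct$estimate), p.value = ct$p.value)
    })
    fam$p.holm <- stats::p.adjust(fam$p.value, method = "holm")
    fam$significant <- fam$p.holm < alpha
    fam
  })
}

#' Holm-Bonferroni rejection decisions
#'
#' Step-down familywise error control: the ordered p-values are compared to
#' `alpha / (m - rank + 1)` and testing stops at the first failure.
#' Implemented through [stats::p.adjust()].
#'
#' @param p Vector of p-values (one family).
#' @param alpha Familywise level.
#' @return Logical vector, `TRUE` where the hypothesis is rejected.
#' @export
holm_reject <- function(p, alpha = 0.05) {
  stats::p.adjust(p, method = "holm") < alpha
}

#' Median-split summary of an outcome by gender
#'
#' Splits a memory score at the whole-sample median (ties go to the low
#' group) and reports the mean and standard error of the outcome in each
#' gender-by-split cell — the descriptive companion to the interaction
#' regressions.
#'
#' @param table Complete analysis tibble.
#' @param score Memory-score column to split on.
#' @param outcome Outcome column to summarize.
#' @return A tibble with one row per gender-by-split cell: `mean`, `se`,
#'   `n`.
#' @export
median_split_summary <- function(table, score, outcome) {
  med <- stats::median(table[[score]])
  table |>
    dplyr::mutate(split = ifelse(.data[[score]] > med, "high", "low")) |>
    dplyr::group_by(.data$gender, .data$split) |>
    dplyr::summarise(
      mean = mean(.data[[outcome]]),
      se = stats::sd(.data[[outcome]]) / sqrt(dplyr::n()),
      n = dplyr::n(),
      .groups = "drop"
    )
}
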