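#' Configuration for a synthetic cohort
#'
#' Collects the generative settings for [generate_cohort()]: cohort size and
#' gender mix, covariate distributions (age, IQ, yearly income with
#' missingness), gender-structured memory scores, and the generative
#' discounting parameters, including an optional gender-by-memory interaction
#' injected into ln(k).
#'
#' Defaults emulate a cohort of 58 healthy older adults (30 women) aged
#' 60-89: women outscore men on all three memory measures, incomes are
#' right-skewed and lower for women, and roughly 10% of incomes are missing
#' completely at random. Memory means/gaps are ordered (FNPA-PF, IGD-C1,
#' IGD-C2).
#'
#' The hyperbolic rate is generated on the log scale,
#' `ln k = lnk_mean + effect_gender_memory_on_lnk * gender_c * igd_c2_c + noise`,
#' with `gender_c` the centered female indicator and `igd_c2_c` the centered
#' IGD-C2 score; a positive slope makes discounting rise with memory in women
#' and fall in men. The quasi-hyperbolic truth (`true_beta`, `true_delta`) is
#' derived from `true_k` by matching the hyperbolic curve at 3 and 12 months,
#' so each participant has one internally consistent level of impatience.
#'
#' @param n_participants Cohort size (>= 2).
#' @param gender_ratio Proportion of women.
#' @param age_range,age_mean,age_sd Age distribution in years (normal,
#'   clamped to `age_range`).
#' @param iq_mean,iq_sd Intelligence screening score distribution.
#' @param income_mean_male,income_mean_female,income_sd Yearly income
#'   (euros); log-normal within gender.
#' @param income_missing_rate Probability an income is missing (MCAR).
#' @param memory_male_mean Male mean of each memory score.
#' @param memory_gender_gap Female minus male mean shift per score (length 1
#'   or 3).
#' @param memory_sd Within-gender SD of each score (length 1 or 3).
#' @param lnk_mean,lnk_sd Mean and SD of ln(k) (k in 1/months).
#' @param effect_gender_memory_on_lnk Interaction slope on ln(k) per unit of
#'   centered-gender times centered IGD-C2.
#' @param choice_temperature Logistic choice sensitivity (1/euro); larger is
#'   more deterministic. May be `Inf`.
#'
#' @return A list of class `cohort_config`.
#' @seealso [generate_cohort()], [simulate_choices()]
#' @export
cohort_config <- function(n_participants = 58,
                          gender_ratio = 30 / 58,
                          age_range = c(60, 89),
                          age_mean = 72.6,
                          age_sd = 6.4,
                          iq_mean = 16.1,
                          iq_sd = 4.6,
                          income_mean_male = 29409,
                          income_mean_female = 15833,
                          income_sd = 12000,
                          income_missing_rate = 6 / 58,
                          memory_male_mean = c(0.33, 1.62, 1.66),
                          memory_gender_gap = c(0.24, 0.12, 0.11),
                          memory_sd = c(0.21, 0.21, 0.19),
                          lnk_mean = -2,
                          lnk_sd = 1,
                          effect_gender_memory_on_lnk = 0,
                          choice_temperature = 2) {
  cfg <- list(
    n_participants = n_participants, gender_ratio = gender_ratio,
    age_range = age_range, age_mean = age_mean, age_sd = age_sd,
    iq_mean = iq_mean, iq_sd = iq_sd,
    income_mean_male = income_mean_male,
    income_mean_female = income_mean_female,
    income_sd = income_sd, income_missing_rate = income_missing_rate,
    memory_male_mean = rep_len(memory_male_mean, 3),
    memory_gender_gap = rep_len(memory_gender_gap, 3),
    memory_sd = rep_len(memory_sd, 3),
    lnk_mean = lnk_mean, lnk_sd = lnk_sd,
    effect_gender_memory_on_lnk = effect_gender_memory_on_lnk,
    choice_temperature = choice_temperature
  )
  check_config_field(cfg$n_participants >= 2, "n_participants")
  check_config_field(cfg$gender_ratio >= 0 && cfg$gender_ratio <= 1,
                     "gender_ratio")
  check_config_field(cfg$income_missing_rate >= 0 &&
                       cfg$income_missing_rate <= 1, "income_missing_rate")
  check_config_field(all(cfg$memory_sd >= 0), "memory_sd")
  check_config_field(cfg$lnk_sd >= 0, "lnk_sd")
  check_config_field(cfg$choice_temperature > 0, "choice_temperature")
  check_config_field(cfg$age_range[1] < cfg$age_range[2], "age_range")
  structure(cfg, class = "cohort_config")
}

check_config_field <- function(ok, field) {
  if (!isTRUE(ok)) {
    stop("invalid cohort configuration: field `", field, "`", call. = FALSE)
  }
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws one participant per row: gender, age, IQ, yearly income (possibly
#' missing), three memory scores inside their legal ranges (FNPA-PF in
#' \[-1, 1\], IGD scores in \[0, 2\]), and generative discounting truth
#' `true_k`, `true_lnk`, `true_beta`, `true_delta` plus the logistic choice
#' temperature. All draws are reproducible under `seed`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return A tibble with one row per participant (a cohort table); truth
#'   columns are prefixed `true_`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_participants = 20), seed = 1)
#' dplyr::count(cohort, gender)
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  n <- as.integer(config$n_participants)
  n_female <- round(n * config$gender_ratio)

  withr::with_seed(seed, {
    gender <- sample(rep(c("female", "male"), c(n_female, n - n_female)))
    female <- gender == "female"

    age <- pmin(pmax(stats::rnorm(n, config$age_mean, config$age_sd),
                     config$age_range[1]), config$age_range[2])
    iq <- pmax(stats::rnorm(n, config$iq_mean, config$iq_sd), 0)

    inc_mean <- ifelse(female, config$income_mean_female,
                       config$income_mean_male)
    sdlog <- sqrt(log(1 + (config$income_sd / inc_mean)^2))
    meanlog <- log(inc_mean) - sdlog^2 / 2
    income <- stats::rlnorm(n, meanlog, sdlog)
    income_obs <- income
    income_obs[stats::runif(n) < config$income_missing_rate] <- NA_real_

    gap <- ifelse(female, 1, 0)
    mem <- vapply(1:3, function(j) {
      m <- config$memory_male_mean[j] + gap * config$memory_gender_gap[j]
      stats::rnorm(n, m, config$memory_sd[j])
    }, numeric(n))
    fnpa_pf <- pmin(pmax(mem[, 1], -1), 1)
    igd_c1 <- pmin(pmax(mem[, 2], 0), 2)
    igd_c2 <- pmin(pmax(mem[, 3], 0), 2)

    gender_c <- (female - mean(female))
    igd_c2_c <- igd_c2 - mean(igd_c2)
    lnk <- config$lnk_mean +
      config$effect_gender_memory_on_lnk * gender_c * igd_c2_c +
      stats::rnorm(n, 0, config$lnk_sd)
    k <- exp(lnk)
    bd <- beta_delta_from_k(k)
  })

  tibble::tibble(
    participant_id = sprintf("p%03d", seq_len(n)),
    gender = gender,
    age = age,
    iq = iq,
    income = income_obs,
    fnpa_pf = fnpa_pf,
    igd_c1 = igd_c1,
    igd_c2 = igd_c2,
    true_income = income,
    true_k = k,
    true_lnk = lnk,
    true_beta = bd$beta,
    true_delta = bd$delta,
    choice_temperature = config$choice_temperature
  )
}

# quasi-hyperbolic parameters whose curve meets the hyperbolic one at
# 3 and 12 months: delta = (sv12/sv3)^(1/9), beta = sv3 / delta^3
beta_delta_from_k <- function(k) {
  sv3 <- 1 / (1 + 3 * k)
  sv12 <- 1 / (1 + 12 * k)
  delta <- (sv12 / sv3)^(1 / 9)
  beta <- pmin(sv3 / delta^3, 1)
  list(beta = beta, delta = pmin(delta, 1))
}

#' Simulate binary choices from the beta-delta model
#'
#' Fills the `choice` column of a trial design. Both options are valued
#' under the quasi-hyperbolic discount: an amount `A` at delay `T` months is
#' worth `A` when `T = 0` ("tomorrow") and `A * beta * delta^T` otherwise —
#' the sooner option in the 6-versus-9/12-month blocks is itself discounted.
#' The later option is chosen with probability
#' `plogis(temperature * (SV_later - SV_sooner))` (euro units); at infinite
#' temperature the higher-valued option is chosen outright and exact ties
#' are resolved by a fair coin.
#'
#' @param truth A one-row cohort table (or list) with `true_beta`,
#'   `true_delta` and `choice_temperature`.
#' @param design Trial tibble from [build_choice_design()].
#' @param seed Integer seed.
#' @return `design` with `choice` filled with "sooner"/"later".
#' @export
simulate_choices <- function(truth, design, seed = 1) {
  need <- c("sooner_amount", "later_amount", "sooner_delay", "later_delay")
  if (!all(need %in% names(design)) ||
      anyNA(design[need])) {
    stop("malformed design: amounts and delays must be present and complete",
         call. = FALSE)
  }
  beta <- truth$true_beta[1]
  delta <- truth$true_delta[1]
  temp <- truth$choice_temperature[1]
  stopifnot(beta >= 0, beta <= 1, delta >= 0, delta <= 1, temp >= 0)

  disc <- function(t) ifelse(t == 0, 1, beta * delta^t)
  sv_sooner <- design$sooner_amount * disc(design$sooner_delay)
  sv_later <- design$later_amount * disc(design$later_delay)
  dv <- sv_later - sv_sooner
  p_later <- if (is.infinite(temp)) {
    (sign(dv) + 1) / 2   # ties at 0.5
  } else {
    stats::plogis(temp * dv)
  }
  withr::with_seed(seed, {
    design$choice <- ifelse(stats::runif(nrow(design)) < p_later,
                            "later", "sooner")
  })
  design
}

#' Simulate a full cohort's trial data
#'
#' Builds one task design per participant and simulates all choices. Each
#' participant draws design and response seeds from a substream table derived
#' from the root seed, so enlarging the cohort leaves earlier participants'
#' data unchanged.
#'
#' @param cohort Cohort table from [generate_cohort()].
#' @param seed Integer root seed.
#' @return A tibble of trials for all participants with choices filled.
#' @export
simulate_cohort_choices <- function(cohort, seed = 1) {
  n <- nrow(cohort)
  # one row of (design, choice) seeds per participant, drawn row-wise so a
  # larger cohort reuses the same substreams for its shared prefix
  seeds <- withr::with_seed(seed, {
    matrix(sample.int(.Machine$integer.max, 2 * n), ncol = 2, byrow = TRUE)
  })
  purrr::map_dfr(seq_len(n), function(i) {
    design <- build_choice_design(cohort$participant_id[i], seeds[i, 1])
    simulate_choices(cohort[i, ], design, seeds[i, 2])
  })
}
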