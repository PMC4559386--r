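#' Per-block indifference point from binary choices
#'
#' Fits the psychometric function `P(choose sooner) = logistic(a + b *
#' sooner_amount)` to one block of 18 choices by maximum likelihood and
#' returns the amount at which both options are equally likely to be chosen,
#' `IP = -a / b`, clipped to the 0-20 euro range. Catch trials are included:
#' the dominated 0- and 20-euro offers anchor both ends of the curve.
#'
#' With only 18 trials, deterministic responders are common and the
#' likelihood has no finite maximum (perfect separation). In that case — or
#' when the fitted slope is non-positive or non-finite — a model-free
#' fallback is used: `IP = 2.5 * sum_a p_later(a) - 1.25`, the choice-curve
#' area over the nine amounts. For a monotone deterministic responder this
#' equals the midpoint between the largest amount at which the later option
#' was always taken and the smallest at which the sooner option was always
#' taken; an all-later responder gets IP = 20 and an all-sooner responder
#' IP = 0 after clipping.
#'
#' @param block_trials Tibble of 18 trials from one block, choices filled.
#' @return One-row tibble: `ip_euros`, `ip_proportion` (= `ip_euros / 20`),
#'   `slope`, `intercept`, `separated` (fallback used).
#' @export
estimate_ip <- function(block_trials) {
  if (nrow(block_trials) != 18) {
    stop("malformed block: expected 18 trials, got ", nrow(block_trials),
         call. = FALSE)
  }
  if (anyNA(block_trials$choice)) {
    stop("malformed block: missing choices", call. = FALSE)
  }
  sooner <- as.integer(block_trials$choice == "sooner")
  amount <- block_trials$sooner_amount

  # perfect separation (including all-same-choice blocks): some threshold
  # splits later- from sooner-choices cleanly, so the likelihood has no
  # finite maximum
  degenerate <- !any(sooner == 1) || all(sooner == 1) ||
    max(amount[sooner == 0]) < min(amount[sooner == 1])
  a <- b <- NA_real_
  if (!degenerate) {
    fit <- withCallingHandlers(
      stats::glm(sooner ~ amount, family = stats::binomial()),
      warning = function(w) invokeRestart("muffleWarning")
    )
    a <- unname(stats::coef(fit)[1])
    b <- unname(stats::coef(fit)[2])
    # a huge |slope| signals quasi-separation: the ML estimate is diverging
    degenerate <- !fit$converged || !is.finite(a) || !is.finite(b) ||
      b <= 0 || abs(b) > 10
  }

  if (degenerate) {
    p_later <- tapply(1 - sooner, amount, mean)
    ip <- 2.5 * sum(p_later) - 1.25
    a <- NA_real_
    b <- NA_real_
  } else {
    ip <- -a / b
  }
  tibble::tibble(
    ip_euros = min(max(ip, 0), 20),
    ip_proportion = min(max(ip, 0), 20) / 20,
    slope = b,
    intercept = a,
    separated = degenerate
  )
}

#' Indifference profiles for a cohort
#'
#' Applies [estimate_ip()] to every participant-by-block cell of a trial
#' table and converts indifference points to proportions of the fixed
#' 20-euro delayed reward.
#'
#' @param trials Trial tibble with choices (all participants).
#' @return A tibble with one row per participant and block: delays, IP in
#'   euros and as a proportion, logistic coefficients, and the `separated`
#'   fallback flag.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_participants = 2), seed = 1)
#' trials <- simulate_cohort_choices(cohort, seed = 1)
#' estimate_indifference(trials)
#' @export
estimate_indifference <- function(trials) {
  trials |>
    dplyr::group_by(.data$participant_id, .data$block,
                    .data$sooner_delay, .data$later_delay) |>
    dplyr::group_modify(~ estimate_ip(.x)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$participant_id, .data$block)
}
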