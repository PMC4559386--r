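#' Hyperbolic subjective value
#'
#' `SV(T) = 1 / (1 + k T)` for a unit reward at delay `T` months. Larger `k`
#' means steeper discounting.
#'
#' @param k Discount rate (>= 0, 1/months).
#' @param t Delay in months (>= 0); vectorized.
#' @return Subjective value in (0, 1].
#' @export
sv_hyperbolic <- function(k, t) {
  if (any(k < 0) || any(t < 0)) {
    stop("invalid input: k and t must be non-negative", call. = FALSE)
  }
  1 / (1 + k * t)
}

#' Quasi-hyperbolic (beta-delta) subjective value
#'
#' `SV(0) = 1` and `SV(T) = beta * delta^T` for `T > 0`, for a unit reward.
#' `beta` indexes present-bias (smaller values mean a larger premium on
#' immediacy); `delta` indexes long-run patience, with discount rate
#' `log(1/delta)` per month.
#'
#' @param beta,delta Parameters in \[0, 1\].
#' @param t Delay in months (>= 0); vectorized.
#' @return Subjective value in \[0, 1\].
#' @export
sv_quasihyperbolic <- function(beta, delta, t) {
  if (any(beta < 0) || any(beta > 1) || any(delta < 0) || any(delta > 1) ||
      any(t < 0)) {
    stop("invalid input: need 0 <= beta, delta <= 1 and t >= 0",
         call. = FALSE)
  }
  ifelse(t == 0, 1, beta * delta^t)
}

# delays (months) of the four model-fitted indifference points
.fit_delays <- c(3, 6, 9, 12)

#' Fit the hyperbolic model to four indifference points
#'
#' Minimizes the sum of squared errors between the indifference-point
#' proportions at 3, 6, 9 and 12 months and `1 / (1 + k T)` over
#' `k` in \[0, 10\] (1/months). A log-spaced multi-start grid is refined by
#' bounded one-dimensional optimization; the best SSE wins.
#'
#' @param ips Four proportions in \[0, 1\] at delays 3, 6, 9, 12 months.
#' @return A list with `k` and `sse`.
#' @examples
#' fit_hyperbolic(1 / (1 + 0.2 * c(3, 6, 9, 12)))
#' @export
fit_hyperbolic <- function(ips) {
  check_ips(ips)
  sse <- function(k) sum((ips - 1 / (1 + k * .fit_delays))^2)
  grid <- c(0, 10^seq(-4, 1, length.out = 60))
  vals <- vapply(grid, sse, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(i - 1, 1)]
  hi <- grid[min(i + 1, length(grid))]
  best <- list(k = grid[i], sse = vals[i])
  if (hi > lo) {
    opt <- stats::optimize(sse, c(lo, hi), tol = 1e-10)
    if (opt$objective < best$sse) {
      best <- list(k = opt$minimum, sse = opt$objective)
    }
  }
  best
}

#' Fit the quasi-hyperbolic (beta-delta) model to four indifference points
#'
#' Minimizes the sum of squared errors between the indifference-point
#' proportions at 3, 6, 9 and 12 months and `beta * delta^T` over the unit
#' square. A coarse grid multi-start is refined by bounded (L-BFGS-B)
#' optimization from the best starting points; the best SSE wins.
#'
#' @param ips Four proportions in \[0, 1\] at delays 3, 6, 9, 12 months.
#' @return A list with `beta`, `delta` and `sse`.
#' @examples
#' fit_quasihyperbolic(0.7 * 0.98^c(3, 6, 9, 12))
#' @export
fit_quasihyperbolic <- function(ips) {
  check_ips(ips)
  sse <- function(p) sum((ips - p[1] * p[2]^.fit_delays)^2)
  grid <- expand.grid(beta = seq(0, 1, by = 0.05),
                      delta = seq(0, 1, by = 0.02))
  vals <- apply(grid, 1, sse)
  ord <- order(vals)
  best <- list(beta = grid$beta[ord[1]], delta = grid$delta[ord[1]],
               sse = vals[ord[1]])
  for (j in ord[1:5]) {
    opt <- stats::optim(c(grid$beta[j], grid$delta[j]), sse,
                        method = "L-BFGS-B", lower = c(0, 0), upper = c(1, 1),
                        control = list(factr = 1e3))
    if (opt$value < best$sse) {
      best <- list(beta = opt$par[1], delta = opt$par[2], sse = opt$value)
    }
  }
  best
}

check_ips <- function(ips) {
  if (length(ips) != 4 || anyNA(ips) || any(ips < 0) || any(ips > 1)) {
    stop("invalid input: need 4 indifference-point proportions in [0, 1]",
         call. = FALSE)
  }
}

#' AIC for a least-squares fit
#'
#' Gaussian least-squares form `AIC = n * log(SSE / n) + 2 p`. The SSE is
#' floored at 1e-10 before the log so that exact fits remain comparable.
#'
#' @param sse Residual sum of squares (>= 0).
#' @param n_points Number of fitted points.
#' @param n_params Number of free parameters.
#' @return The AIC value.
#' @export
aic_ls <- function(sse, n_points, n_params) {
  if (n_points <= 0) stop("invalid input: n_points must be positive",
                          call. = FALSE)
  n_points * log(max(sse, 1e-10) / n_points) + 2 * n_params
}

#' Count impulsive choices
#'
#' The model-free impulsivity index NImp: the number of sooner-option
#' choices on the 84 non-catch trials of a participant's session.
#'
#' @param trials One participant's trial tibble with choices.
#' @return Integer count in \[0, 84\].
#' @export
count_impulsive <- function(trials) {
  free <- dplyr::filter(trials, !.data$is_catch)
  if (anyNA(free$choice)) {
    stop("incomplete data: missing choices on non-catch trials",
         call. = FALSE)
  }
  sum(free$choice == "sooner")
}

#' Discounting fits for a cohort
#'
#' For each participant, fits the hyperbolic and quasi-hyperbolic models to
#' the four tomorrow-anchored indifference points (blocks 1-4, delays 3, 6,
#' 9, 12 months; the 6-month-anchored blocks 5-6 are excluded from fitting),
#' compares the models by least-squares AIC, and counts impulsive choices.
#' `ln_k` is `log(max(k, 1e-4))`: the floor keeps the log defined at the
#' patient boundary `k = 0`.
#'
#' @param ips Indifference table from [estimate_indifference()].
#' @param trials Trial tibble with choices (for NImp); optional.
#' @return A tibble with one row per participant: `k`, `ln_k`, `beta`,
#'   `delta`, per-model SSE and AIC, `preferred_model`, and `n_imp` (NA when
#'   `trials` is not supplied).
#' @examples
#' cohort <- generate_cohort(cohort_config(n_participants = 2), seed = 1)
#' trials <- simulate_cohort_choices(cohort, seed = 1)
#' fit_discounting(estimate_indifference(trials), trials)
#' @export
fit_discounting <- function(ips, trials = NULL) {
  nimp <- if (is.null(trials)) {
    NULL
  } else {
    trials |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::summarise(n_imp = count_impulsive(dplyr::pick(dplyr::everything())),
                       .groups = "drop")
  }
  fits <- ips |>
    dplyr::filter(.data$block %in% 1:4) |>
    dplyr::arrange(.data$participant_id, .data$block) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(function(d, key) {
      stopifnot(nrow(d) == 4)
      hyp <- fit_hyperbolic(d$ip_proportion)
      qh <- fit_quasihyperbolic(d$ip_proportion)
      aic_h <- aic_ls(hyp$sse, 4, 1)
      aic_q <- aic_ls(qh$sse, 4, 2)
      tibble::tibble(
        k = hyp$k, ln_k = log(max(hyp$k, 1e-4)),
        beta = qh$beta, delta = qh$delta,
        sse_hyp = hyp$sse, sse_qh = qh$sse,
        aic_hyp = aic_h, aic_qh = aic_q,
        preferred_model = ifelse(aic_q < aic_h, "quasi-hyperbolic",
                                 "hyperbolic")
      )
    }) |>
    dplyr::ungroup()
  if (!is.null(nimp)) fits <- dplyr::left_join(fits, nimp,
                                               by = "participant_id")
  fits
}
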