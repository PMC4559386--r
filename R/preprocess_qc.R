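#' Score catch trials and flag inattentive participants
#'
#' Catch trials have a logically dominant option: 0-now versus 20-later
#' should elicit the later choice, and 20-now versus 20-later the sooner
#' (immediate) choice. A participant is excluded when more than half of
#' their catch trials are answered against the dominant option — with the
#' standard 6-block design that is 13 or more of 24.
#'
#' @param trials Trial tibble with choices for one or more participants.
#' @return A tibble with one row per participant: `participant_id`,
#'   `n_catch`, `n_catch_incorrect`, `excluded`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_participants = 4), seed = 1)
#' trials <- simulate_cohort_choices(cohort, seed = 1)
#' score_catch_trials(trials)
#' @export
score_catch_trials <- function(trials) {
  catch <- dplyr::filter(trials, .data$is_catch)
  if (anyNA(catch$choice)) {
    stop("incomplete data: catch trials with missing choices", call. = FALSE)
  }
  catch |>
    dplyr::mutate(
      correct = ifelse(.data$sooner_amount == 0,
                       .data$choice == "later",
                       .data$choice == "sooner")
    ) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_catch = dplyr::n(),
      n_catch_incorrect = sum(!.data$correct),
      .groups = "drop"
    ) |>
    dplyr::mutate(excluded = .data$n_catch_incorrect > .data$n_catch / 2)
}

#' Drop excluded participants from an analysis table
#'
#' @param table Per-participant tibble with a `participant_id` column.
#' @param qc QC report from [score_catch_trials()].
#' @return `table` restricted to QC-passing participants.
#' @export
apply_exclusions <- function(table, qc) {
  keep <- qc$participant_id[!qc$excluded]
  dplyr::filter(table, .data$participant_id %in% keep)
}
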