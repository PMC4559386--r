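#' Intertemporal choice task design
#'
#' Builds the per-trial layout of the six-block intertemporal choice task.
#' The later option is always 20 euro; the sooner option runs over the nine
#' amounts 0, 2.50, ..., 20 euro, each presented twice per block (18 trials
#' per block, 108 in total). In blocks 1-4 the sooner option is available
#' "tomorrow" (encoded as a delay of 0 months) and the later option at 3, 6,
#' 9 or 12 months; in blocks 5 and 6 the sooner option is itself delayed by
#' 6 months against later delays of 9 and 12 months. Trials whose sooner
#' amount is 0 or 20 euro are catch trials: one option dominates (0 now vs
#' 20 later, or 20 now vs 20 later), so they probe attention rather than
#' preference.
#'
#' Block presentation order, trial order within block, and the screen side of
#' the sooner option are randomized under `seed`; the design counts are
#' identical for every seed.
#'
#' @param participant_id Identifier copied into every row.
#' @param seed Integer seed controlling block order, trial order and side
#'   allocation.
#'
#' @return A tibble with one row per trial, in presentation order, with
#'   columns `participant_id`, `presentation_order`, `block`, `sooner_delay`,
#'   `later_delay` (months; 0 encodes "tomorrow"), `sooner_amount`,
#'   `later_amount` (euros), `is_catch`, `side_of_sooner` ("left"/"right")
#'   and `choice` (`NA` until filled by a responder or by
#'   [simulate_choices()]).
#'
#' @examples
#' design <- build_choice_design("p01", seed = 1)
#' nrow(design)                 # 108
#' sum(design$is_catch)         # 24
#' @export
build_choice_design <- function(participant_id, seed) {
  stopifnot(length(participant_id) == 1, length(seed) == 1)
  amounts <- seq(0, 20, by = 2.5)
  delays <- tibble::tibble(
    block = 1:6,
    sooner_delay = c(0, 0, 0, 0, 6, 6),
    later_delay = c(3, 6, 9, 12, 9, 12)
  )

  withr::with_seed(seed, {
    block_order <- sample(1:6)
    trials <- purrr::map_dfr(block_order, function(b) {
      d <- delays[delays$block == b, ]
      tibble::tibble(
        block = b,
        sooner_delay = d$sooner_delay,
        later_delay = d$later_delay,
        sooner_amount = sample(rep(amounts, 2)),
        later_amount = 20,
        side_of_sooner = sample(c("left", "right"), 18, replace = TRUE)
      )
    })
  })

  trials |>
    dplyr::mutate(
      participant_id = participant_id,
      presentation_order = dplyr::row_number(),
      is_catch = .data$sooner_amount %in% c(0, 20),
      choice = NA_character_,
      .before = 1
    ) |>
    dplyr::relocate("participant_id", "presentation_order", "block")
}

#' Face-name paired-associates (FNPA) design
#'
#' Lays out the retrieval trials of the face-name paired-associates task:
#' 40 unique faces split into 4 blocks of 10; at retrieval, half the pairs
#' in each block are intact (the studied face-name pairing) and half are
#' recombined with another name from the same block. Intact pairs judged
#' "correct" are hits; recombined pairs judged "correct" are false alarms.
#'
#' @param seed Integer seed controlling which pairs are recombined and how.
#'
#' @return A list with elements `n_blocks`, `retrieval_trials_per_block`,
#'   `fraction_correct_pairs`, `n_faces`, and `layout`, a 40-row tibble with
#'   columns `block`, `face_id`, `studied_name_id`, `shown_name_id` and
#'   `is_correct_pair`.
#'
#' @examples
#' fnpa <- build_fnpa_design(seed = 1)
#' table(fnpa$layout$block, fnpa$layout$is_correct_pair)
#' @export
build_fnpa_design <- function(seed) {
  stopifnot(length(seed) == 1)
  layout <- withr::with_seed(seed, {
    purrr::map_dfr(1:4, function(b) {
      faces <- (b - 1) * 10 + 1:10
      correct <- sort(sample(1:10, 5))
      shown <- faces
      # recombine the 5 false pairs among themselves, within block, with no
      # pair left intact (a derangement of the false subset)
      false_idx <- setdiff(1:10, correct)
      shown[false_idx] <- faces[false_idx[derangement(5)]]
      tibble::tibble(
        block = b,
        face_id = faces,
        studied_name_id = faces,
        shown_name_id = shown,
        is_correct_pair = seq_along(faces) %in% correct
      )
    })
  })
  list(
    n_blocks = 4L,
    retrieval_trials_per_block = 10L,
    fraction_correct_pairs = 0.5,
    n_faces = 40L,
    layout = layout
  )
}

# random derangement of 1:n by rejection
derangement <- function(n) {
  repeat {
    p <- sample(n)
    if (all(p != seq_len(n))) return(p)
  }
}
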