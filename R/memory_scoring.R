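#' Face-name paired-associates performance (FNPA-PF)
#'
#' Hits minus false alarms on the proportion scale: `hits/20 -
#' false_alarms/20`, where the four retrieval blocks together contain 20
#' intact and 20 recombined face-name pairs. Ranges from -1 (every
#' recombined pair endorsed, every intact pair rejected) through 0 (chance)
#' to 1 (perfect).
#'
#' @param hits Intact pairs judged correct (0-20); vectorized.
#' @param false_alarms Recombined pairs judged correct (0-20); vectorized.
#' @return Score in \[-1, 1\].
#' @examples
#' fnpa_pf(hits = 20, false_alarms = 0)   # 1
#' fnpa_pf(hits = 9, false_alarms = 0)    # 0.45
#' @export
fnpa_pf <- function(hits, false_alarms) {
  if (any(hits < 0 | hits > 20) || any(false_alarms < 0 | false_alarms > 20)) {
    stop("invalid input: hits and false_alarms must lie in [0, 20]",
         call. = FALSE)
  }
  hits / 20 - false_alarms / 20
}

#' Autobiographical event-memory score (IGD-C1)
#'
#' Personal-event recall over four life episodes (up to 5 events each,
#' maximum 20), plus one vividness/specificity/emotionality rating triple
#' per episode on 0-3 scales (maximum 4 episodes x 3 ratings x 3 = 36):
#' `sum(events)/20 + sum(ratings)/36`, range 0-2.
#'
#' @param events Counts of recalled events per episode, each in \[0, 5\]
#'   (any length summing to at most 20).
#' @param ratings Quality ratings, each in \[0, 3\], summing to at most 36.
#' @return Score in \[0, 2\].
#' @examples
#' igd_c1(events = c(5, 5, 5, 5), ratings = rep(3, 12))   # 2
#' @export
igd_c1 <- function(events, ratings) {
  if (any(events < 0 | events > 5) || sum(events) > 20) {
    stop("invalid input: events must lie in [0, 5] and sum to <= 20",
         call. = FALSE)
  }
  if (any(ratings < 0 | ratings > 3) || sum(ratings) > 36) {
    stop("invalid input: ratings must lie in [0, 3] and sum to <= 36",
         call. = FALSE)
  }
  sum(events) / 20 + sum(ratings) / 36
}

#' Autobiographical fact-and-date score, "personal semantics" (IGD-C2)
#'
#' Of the 64 yes/no items about general life-related topics, only items
#' that apply to the participant are answered. The score is the proportion
#' of answered items endorsed "yes" plus the proportion of the confidence
#' rating actually awarded relative to its maximum (each yes-item rated
#' 0-3): `yes_count/answered + sum(confidence)/(3 * yes_count)`, range 0-2;
#' with no yes-answers the confidence term is 0.
#'
#' @param answered Number of answered items (1-64).
#' @param yes_count Number of "yes" answers (<= answered).
#' @param confidence Confidence ratings for the yes-items, each in \[0, 3\].
#' @return Score in \[0, 2\].
#' @examples
#' igd_c2(answered = 64, yes_count = 32, confidence = rep(1.5, 32))   # 1.0
#' @export
igd_c2 <- function(answered, yes_count, confidence = numeric(0)) {
  if (answered < 1 || answered > 64) {
    stop("invalid input: answered must lie in [1, 64]", call. = FALSE)
  }
  if (yes_count < 0 || yes_count > answered) {
    stop("invalid input: need 0 <= yes_count <= answered", call. = FALSE)
  }
  if (length(confidence) > yes_count ||
      any(confidence < 0 | confidence > 3)) {
    stop("invalid input: one confidence rating in [0, 3] per yes-item",
         call. = FALSE)
  }
  conf_prop <- if (yes_count == 0) 0 else sum(confidence) / (3 * yes_count)
  yes_count / answered + conf_prop
}

#' Score a table of raw memory responses
#'
#' Convenience wrapper computing all three scores from a per-participant
#' table of raw instrument responses.
#'
#' @param responses Tibble with one row per participant and columns
#'   `participant_id`, `fnpa_hits`, `fnpa_fa`, `igd_c1_events` and
#'   `igd_c1_ratings` (list-columns or totals), `igd_c2_answered`,
#'   `igd_c2_yes`, `igd_c2_confidence` (list-column or total).
#' @return Tibble with `participant_id`, `fnpa_pf`, `igd_c1`, `igd_c2`.
#' @export
score_memory <- function(responses) {
  as_num <- function(x) if (is.list(x)) x else as.list(x)
  purrr::pmap_dfr(
    list(responses$participant_id, responses$fnpa_hits, responses$fnpa_fa,
         as_num(responses$igd_c1_events), as_num(responses$igd_c1_ratings),
         responses$igd_c2_answered, responses$igd_c2_yes,
         as_num(responses$igd_c2_confidence)),
    function(id, hits, fa, ev, rat, ans, yes, conf) {
      tibble::tibble(
        participant_id = id,
        fnpa_pf = fnpa_pf(hits, fa),
        igd_c1 = igd_c1(ev, rat),
        igd_c2 = igd_c2(ans, yes, conf)
      )
    }
  )
}
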