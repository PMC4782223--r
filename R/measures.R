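#' Partial-credit-unit score for the operation span task
#'
#' The working-memory-capacity score is the mean, over the recall sets,
#' of the proportion of items recalled correctly within each set:
#' `mean(n_correct / set_size)`. Set sizes in the task run from three to
#' seven equation-letter successions.
#'
#' @param sets A data frame with columns `set_size` and `n_correct`
#'   (one row per recall set), or a numeric matrix/list coercible to one.
#' @return The PCU score, a single value in `[0, 1]`.
#' @examples
#' pcu_score(data.frame(set_size = c(3, 4), n_correct = c(3, 2)))  # 0.75
#' @export
pcu_score <- function(sets) {
  sets <- as.data.frame(sets)
  if (!nrow(sets)) stop("no recall sets supplied", call. = FALSE)
  stopifnot(all(c("set_size", "n_correct") %in% names(sets)))
  if (any(sets$set_size < 1) || any(sets$n_correct < 0) ||
      any(sets$n_correct > sets$set_size)) {
    stop("need 0 <= n_correct <= set_size for every set", call. = FALSE)
  }
  mean(sets$n_correct / sets$set_size)
}

#' Score recalled letters against a presented set
#'
#' Strict scoring counts a letter as correct only in its serial position
#' (recall is instructed "in order of presentation"); lenient scoring
#' counts any presented letter recalled anywhere in the response.
#'
#' @param presented Character vector of presented letters, in order.
#' @param recalled Character vector of the typed response, in order.
#' @param lenient If `TRUE`, ignore serial position.
#' @return The number of correctly recalled items (for use as
#'   `n_correct` in [pcu_score()]).
#' @export
score_span_set <- function(presented, recalled, lenient = FALSE) {
  if (lenient) {
    return(sum(!is.na(match(unique(recalled), presented))))
  }
  m <- min(length(presented), length(recalled))
  if (m == 0) return(0L)
  sum(presented[seq_len(m)] == recalled[seq_len(m)])
}

#' Reading fluency from rapid-automatized-naming trials
#'
#' Each trial presents a fixed number of items (50 in the task used here)
#' read aloud against the clock. The per-item reading time is averaged
#' over trials and its reciprocal is returned, so higher values mean more
#' fluent reading, in characters per second.
#'
#' @param trials A data frame with columns `n_items` and `elapsed`
#'   (seconds per trial).
#' @return Fluency in characters/second.
#' @examples
#' ran_fluency(data.frame(n_items = 50, elapsed = 20))  # 2.5 chars/s
#' @export
ran_fluency <- function(trials) {
  trials <- as.data.frame(trials)
  if (!nrow(trials)) stop("no trials supplied", call. = FALSE)
  stopifnot(all(c("n_items", "elapsed") %in% names(trials)))
  if (any(trials$elapsed <= 0) || any(trials$n_items < 1)) {
    stop("elapsed must be positive and n_items >= 1", call. = FALSE)
  }
  1 / mean(trials$elapsed / trials$n_items)
}

#' Score a cohort of participants from trial-level task data
#'
#' Convenience wrapper producing the participant covariate table consumed
#' by [generate_dataset()] and [build_design()].
#'
#' @param span_sets Data frame with columns `participant`, `set_size`,
#'   `n_correct`.
#' @param ran_trials Data frame with columns `participant`, `n_items`,
#'   `elapsed`.
#' @return A tibble with `participant`, `wmc_score` (PCU) and `rf_score`
#'   (chars/s), restricted to participants present in both tables.
#' @export
score_participants <- function(span_sets, ran_trials) {
  ids <- intersect(unique(span_sets$participant),
                   unique(ran_trials$participant))
  if (!length(ids)) stop("no participants common to both tables",
                         call. = FALSE)
  tibble::tibble(
    participant = ids,
    wmc_score = vapply(ids, function(id) {
      pcu_score(span_sets[span_sets$participant == id, ])
    }, numeric(1)),
    rf_score = vapply(ids, function(id) {
      ran_fluency(ran_trials[ran_trials$participant == id, ])
    }, numeric(1))
  )
}
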