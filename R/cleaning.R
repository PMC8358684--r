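#' Screen out low-effort essays
#'
#' An essay is removed when it both contains fewer than 30 pause events
#' *and* received human scores of 0; every other essay is kept. Under the
#' primary reading "scores of 0" means both strand scores are 0; set
#' `score_rule = "either"` for the sensitivity reading (either strand 0).
#'
#' @param corpus a `"pause_corpus"` or plain list of essay records (each
#'   with `pauses`, `strand1`, `strand3`).
#' @param min_events removal threshold on the pause-event count; "fewer
#'   than 30" is strict, so an essay with exactly 30 events is kept.
#' @param score_rule `"both"` (primary) or `"either"`.
#' @return list with `kept` and `removed` (same structure as the input
#'   corpus) and `report`: `n_input`, `n_kept`, `n_removed`,
#'   `removed_fraction`, and the characters-per-pause ratios
#'   `kept_ratio` / `removed_ratio` (NA where undefined).
#' @export
filter_essays <- function(corpus, min_events = 30L,
                          score_rule = c("both", "either")) {
  score_rule <- match.arg(score_rule)
  essays <- corpus_essays(corpus)
  if (!length(essays))
    stop("filter_essays: empty corpus", call. = FALSE)
  n_ev <- vapply(essays, function(e) nrow(e$pauses), integer(1))
  s1 <- vapply(essays, `[[`, numeric(1), "strand1")
  s3 <- vapply(essays, `[[`, numeric(1), "strand3")
  zero_scores <- if (score_rule == "both") s1 == 0 & s3 == 0 else
    s1 == 0 | s3 == 0
  drop <- (n_ev < min_events) & zero_scores
  kept <- subset_corpus(corpus, !drop)
  removed <- subset_corpus(corpus, drop)
  report <- list(
    n_input = length(essays), n_kept = sum(!drop), n_removed = sum(drop),
    removed_fraction = mean(drop),
    kept_ratio = if (any(!drop))
      tryCatch(char_pause_ratio(kept), error = function(e) NA_real_)
      else NA_real_,
    removed_ratio = if (any(drop))
      tryCatch(char_pause_ratio(removed), error = function(e) NA_real_)
      else NA_real_,
    min_events = min_events, score_rule = score_rule)
  list(kept = kept, removed = removed, report = report)
}

#' Characters-per-pause ratio of a corpus
#'
#' The ratio of the mean number of characters typed to the mean number of
#' pause events across essays. Low-effort essays (few or zero pauses for
#' the characters they contain) push this ratio far above the ordinary
#' range, which is the diagnostic the screening rule rests on.
#'
#' @param corpus a `"pause_corpus"` or list of essay records.
#' @return numeric scalar `(mean characters) / (mean pause events)`.
#' @export
char_pause_ratio <- function(corpus) {
  essays <- corpus_essays(corpus)
  if (!length(essays))
    stop("char_pause_ratio: empty corpus", call. = FALSE)
  mean_chars <- mean(vapply(essays, `[[`, numeric(1), "n_chars_typed"))
  mean_pauses <- mean(vapply(essays, function(e) nrow(e$pauses),
                             integer(1)))
  if (mean_pauses == 0)
    stop("char_pause_ratio: mean pause count is zero (degenerate ratio)",
         call. = FALSE)
  mean_chars / mean_pauses
}

# accept either a pause_corpus or a bare list of essay records
corpus_essays <- function(corpus) {
  if (inherits(corpus, "pause_corpus")) corpus$essays else corpus
}

subset_corpus <- function(corpus, keep) {
  if (inherits(corpus, "pause_corpus")) {
    out <- corpus
    out$essays <- corpus$essays[keep]
    if (is.data.frame(corpus$truth) && nrow(corpus$truth))
      out$truth <- corpus$truth[keep, , drop = FALSE]
    out
  } else {
    corpus[keep]
  }
}
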