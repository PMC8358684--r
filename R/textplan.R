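#' Build a typing plan from plain text
#'
#' A *text plan* is the scripted sequence of editor actions used to
#' synthesize a keystroke log: a character vector whose elements are
#' single characters to type (`" "` and `"\n"` become SPACE / ENTER
#' presses) or the action tokens `"<BS>"` (backspace), `"<CUT>"`,
#' `"<PASTE>"`, `"<REPLACE>"`, `"<MOVE>"` (cursor navigation).
#'
#' @param text a character string to be "typed" character by character.
#' @return a text plan (character vector).
#' @examples
#' plan_from_text("ab cd")
#' @export
plan_from_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  strsplit(text, "", fixed = TRUE)[[1L]]
}

plan_token_event <- function(token) {
  switch(token,
         "<BS>" = list(action = "press", key = "BACKSPACE"),
         "<CUT>" = list(action = "cut", key = ""),
         "<PASTE>" = list(action = "paste", key = ""),
         "<REPLACE>" = list(action = "replace", key = ""),
         "<MOVE>" = list(action = "cursor_move", key = ""),
         " " = list(action = "press", key = "SPACE"),
         "\n" = list(action = "press", key = "ENTER"),
         {
           if (nchar(token) != 1L)
             stop("text plan token must be a single character or an ",
                  "action token, got: ", token, call. = FALSE)
           list(action = "press", key = token)
         })
}

#' Synthesize a keystroke log from a text plan
#'
#' Replays a [plan_from_text()]-style script as a time-stamped event
#' stream. The latency preceding each event is drawn from
#' `pause_sampler(context)`, where `context` is the linguistic label that
#' [extract_pauses()] will assign to that interval (or `"(delimiter)"`
#' for intervals ending at SPACE/ENTER, which the parser folds into the
#' following boundary pause). Latencies are rounded to integer
#' milliseconds and floored at 1, so parsing the stream recovers the
#' planted labels and latencies exactly.
#'
#' @param plan a non-empty text plan.
#' @param pause_sampler function taking a context label and returning one
#'   positive latency in ms; default samples lognormal latencies.
#' @param seed optional integer seed.
#' @param t0 timestamp of the first event (ms).
#' @return list with `events` (keystroke-log data frame), `planted`
#'   (data frame `context`, `latency_ms` of the pause events the parser
#'   should recover), and `plan`.
#' @export
generate_keystroke_log <- function(plan, pause_sampler = NULL, seed = NULL,
                                   t0 = 0L) {
  if (!length(plan)) stop("text plan must be non-empty", call. = FALSE)
  if (is.null(pause_sampler))
    pause_sampler <- function(context) exp(stats::rnorm(1L, 5.3, 0.6))
  with_seed(seed, {
    n <- length(plan)
    action <- character(n); key <- character(n)
    ts <- integer(n)
    planted_ctx <- character(0); planted_lat <- numeric(0)
    state <- pause_state_new()
    t <- as.integer(t0)
    for (i in seq_len(n)) {
      ev <- plan_token_event(plan[[i]])
      action[i] <- ev$action; key[i] <- ev$key
      step <- classify_step(state, ev$action, ev$key)
      state <- step$state
      if (i == 1L) {
        ts[i] <- t
        next
      }
      lab <- if (is.na(step$label)) "(delimiter)" else step$label
      lat <- max(1L, as.integer(round(pause_sampler(lab))))
      t <- t + lat
      ts[i] <- t
      if (!is.na(step$label)) {
        planted_ctx <- c(planted_ctx, step$label)
        planted_lat <- c(planted_lat, lat)
      }
    }
    list(events = data.frame(timestamp_ms = ts, action = action, key = key,
                             stringsAsFactors = FALSE),
         planted = data.frame(context = planted_ctx,
                              latency_ms = planted_lat,
                              stringsAsFactors = FALSE),
         plan = plan)
  })
}

#' Draw a random text plan
#'
#' Generates a plausible typing script touching every boundary class:
#' words of random length, sentence punctuation, paragraph breaks,
#' backspace runs and occasional edit operations. Used to exercise the
#' generator/parser round trip.
#'
#' @param n_words number of words to type.
#' @param p_sentence probability a word ends a sentence.
#' @param p_paragraph probability a sentence break is also a paragraph
#'   break.
#' @param p_backspace probability of a backspace run after a word.
#' @param p_edit probability of an edit action after a word.
#' @param seed optional integer seed.
#' @return a text plan.
#' @export
random_text_plan <- function(n_words = 12, p_sentence = 0.25,
                             p_paragraph = 0.25, p_backspace = 0.2,
                             p_edit = 0.1, seed = NULL) {
  with_seed(seed, {
    plan <- character(0)
    for (w in seq_len(n_words)) {
      len <- sample(1:8, 1L)
      plan <- c(plan, sample(letters, len, replace = TRUE))
      if (stats::runif(1) < p_backspace) {
        nb <- sample.int(min(3L, len), 1L)
        plan <- c(plan, rep("<BS>", nb),
                  sample(letters, nb, replace = TRUE))
      }
      if (stats::runif(1) < p_edit)
        plan <- c(plan, sample(c("<CUT>", "<PASTE>", "<REPLACE>",
                                 "<MOVE>"), 1L))
      if (stats::runif(1) < p_sentence) {
        plan <- c(plan, sample(c(".", "?", "!"), 1L))
        if (w < n_words)
          plan <- c(plan,
                    if (stats::runif(1) < p_paragraph) "\n" else " ")
      } else if (w < n_words) {
        plan <- c(plan, " ")
      }
    }
    plan
  })
}
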