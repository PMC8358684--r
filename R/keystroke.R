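#' The eight linguistic pause contexts
#'
#' Pause latencies are classified by the boundary at which they occur:
#' within a word, at word / sentence / paragraph boundaries, around
#' deletions (first backspace of a run, later backspaces of a run, and the
#' resume keypress after a run), or before edit operations (cut, paste,
#' replace, cursor navigation).
#'
#' @format character vector of the eight labels.
#' @export
PAUSE_CONTEXTS <- c("WithinWord", "BackSpace", "BetweenWord",
                    "BetweenSentence", "BetweenParagraph",
                    "MultipleBackspace", "SingleBackspace", "Edit")

EDIT_ACTIONS <- c("cut", "paste", "replace", "cursor_move")
DELIMITER_KEYS <- c("SPACE", "ENTER")

# mutable parser state: committed text buffer and whether the previous
# event was a backspace
pause_state_new <- function() {
  list(text = character(0), prev_backspace = FALSE)
}

# Classify the pause that ends at the event (action, key), given the state
# accumulated over earlier events, then advance the state. Returns
# list(label, state); label is NA for delimiter keypresses (SPACE/ENTER),
# whose intervals are folded into the following boundary pause.
classify_step <- function(state, action, key) {
  label <- NA_character_
  if (action %in% EDIT_ACTIONS) {
    label <- "Edit"
    state$prev_backspace <- FALSE
  } else if (identical(key, "BACKSPACE")) {
    label <- if (state$prev_backspace) "MultipleBackspace" else
      "SingleBackspace"
    if (length(state$text)) state$text <- state$text[-length(state$text)]
    state$prev_backspace <- TRUE
  } else if (key %in% DELIMITER_KEYS) {
    state$text <- c(state$text, if (key == "SPACE") " " else "\n")
    state$prev_backspace <- FALSE
  } else {
    # printing character
    if (state$prev_backspace) {
      label <- "BackSpace"
    } else {
      txt <- state$text
      trail <- character(0)
      while (length(txt) && txt[length(txt)] %in% c(" ", "\n")) {
        trail <- c(txt[length(txt)], trail)
        txt <- txt[-length(txt)]
      }
      if ("\n" %in% trail) {
        label <- "BetweenParagraph"
      } else if (length(txt) && txt[length(txt)] %in% c(".", "?", "!")) {
        label <- "BetweenSentence"
      } else if (length(trail)) {
        label <- "BetweenWord"
      } else {
        label <- "WithinWord"
      }
    }
    state$text <- c(state$text, key)
    state$prev_backspace <- FALSE
  }
  list(label = label, state = state)
}

#' Classify the linguistic context of one pause
#'
#' Applies the precedence rules used throughout the package: (1) *Edit* if
#' the next event is a cut/paste/replace/cursor action; (2)
#' *SingleBackspace* for the first backspace after a non-backspace, (3)
#' *MultipleBackspace* for later backspaces of a run; (4) *BackSpace* for
#' the first printing keypress after a backspace run; (5)
#' *BetweenParagraph* when the interval spans a newline; (6)
#' *BetweenSentence* when the committed text ends with `.`, `?` or `!`
#' plus optional spaces; (7) *BetweenWord* when the interval spans a
#' space; (8) *WithinWord* otherwise. Pauses ending at a SPACE or ENTER
#' keypress are folded into the following boundary pause and classify to
#' `NA`.
#'
#' @param action the next event's action (`"press"`, `"cut"`, `"paste"`,
#'   `"replace"`, `"cursor_move"`).
#' @param key the next event's key (a character, `"BACKSPACE"`, `"SPACE"`,
#'   `"ENTER"`).
#' @param state parser state as built by [extract_pauses()] internals:
#'   list with `text` (committed characters) and `prev_backspace`.
#' @return a single label from [PAUSE_CONTEXTS], or `NA` for a delimiter
#'   keypress.
#' @export
classify_context <- function(action, key, state = pause_state_new()) {
  classify_step(state, action, key)$label
}

#' Extract classified pause events from a keystroke stream
#'
#' Walks consecutive event pairs; every pair with strictly positive
#' latency whose second event is classifiable (printing character,
#' backspace, or edit action) yields one pause event labeled by the rules
#' of [classify_context()]. Zero-latency intervals are dropped as logging
#' artifacts; intervals ending at SPACE/ENTER are folded into the
#' following boundary pause. Order is preserved.
#'
#' @param events data frame with columns `timestamp_ms` (non-negative,
#'   non-decreasing), `action`, `key` (see [read_keystroke_log()]).
#' @return data frame with columns `context`, `latency_ms`.
#' @export
extract_pauses <- function(events) {
  events <- as.data.frame(events)
  need <- c("timestamp_ms", "action", "key")
  if (!all(need %in% names(events)))
    stop("extract_pauses: events need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  ts <- events$timestamp_ms
  if (any(ts < 0))
    stop("extract_pauses: negative timestamp at line ",
         which(ts < 0)[1L], call. = FALSE)
  if (is.unsorted(ts))
    stop("extract_pauses: timestamps out of order at line ",
         which(diff(ts) < 0)[1L] + 1L, call. = FALSE)
  n <- nrow(events)
  state <- pause_state_new()
  ctx <- character(0)
  lat <- numeric(0)
  for (i in seq_len(n)) {
    step <- classify_step(state, events$action[i], events$key[i])
    state <- step$state
    if (i > 1L && !is.na(step$label)) {
      l <- ts[i] - ts[i - 1L]
      if (l > 0) {
        ctx <- c(ctx, step$label)
        lat <- c(lat, l)
      }
    }
  }
  data.frame(context = ctx, latency_ms = lat, stringsAsFactors = FALSE)
}

#' Latencies of one linguistic context
#'
#' The analysis streams one context per dataset (typically *WithinWord*);
#' this filters a pause table down to the latencies of one label,
#' preserving order.
#'
#' @param pauses data frame with columns `context`, `latency_ms`.
#' @param context one of [PAUSE_CONTEXTS].
#' @return numeric vector of latencies (possibly empty).
#' @export
select_context <- function(pauses, context) {
  if (!is.character(context) || length(context) != 1L ||
      !(context %in% PAUSE_CONTEXTS))
    stop("unknown context label: ", context, call. = FALSE)
  pauses$latency_ms[pauses$context == context]
}

#' Read / write a keystroke-log CSV
#'
#' The log dialect has columns `timestamp_ms` (integer, session-relative,
#' non-decreasing), `action` (`press`, `cut`, `paste`, `replace`,
#' `cursor_move`) and `key` (a single character, `"BACKSPACE"`,
#' `"ENTER"`, `"SPACE"`; empty for non-press actions). An optional
#' `essay_id` column allows several essays per file.
#'
#' @param path file path.
#' @param events data frame of events to write.
#' @return `read_keystroke_log()` returns the events data frame.
#' @export
read_keystroke_log <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(timestamp_ms = "integer",
                                       action = "character",
                                       key = "character")[1:0],
                        check.names = FALSE)
  need <- c("timestamp_ms", "action", "key")
  if (!all(need %in% names(ev)))
    stop("keystroke log must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  ev$timestamp_ms <- as.integer(ev$timestamp_ms)
  ev$key[is.na(ev$key)] <- ""
  ev
}

#' @rdname read_keystroke_log
#' @export
write_keystroke_log <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
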