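press <- function(keys, times) {
  data.frame(timestamp_ms = times, action = "press", key = keys,
             stringsAsFactors = FALSE)
}

test_that("classification rules follow the documented precedence", {
  # within a word: letter to letter with no delimiter
  ev <- press(c("a", "b"), c(0, 120))
  p <- extract_pauses(ev)
  expect_equal(p$context, "WithinWord")
  expect_equal(p$latency_ms, 120)

  # backspace run semantics: first = Single, later = Multiple,
  # resume keypress = BackSpace
  ev2 <- press(c("a", "BACKSPACE", "BACKSPACE", "a"),
               c(0, 200, 350, 500))
  p2 <- extract_pauses(ev2)
  expect_equal(p2$context,
               c("SingleBackspace", "MultipleBackspace", "BackSpace"))
  expect_equal(p2$latency_ms, c(200, 150, 150))

  # an edit action takes precedence over everything
  ev3 <- data.frame(timestamp_ms = c(0, 300),
                    action = c("press", "paste"), key = c("a", ""),
                    stringsAsFactors = FALSE)
  expect_equal(extract_pauses(ev3)$context, "Edit")

  # sentence boundary: ". " then a letter
  ev4 <- press(c("a", ".", "SPACE", "b"), c(0, 100, 200, 350))
  p4 <- extract_pauses(ev4)
  expect_equal(p4$context[p4$latency_ms == 150], "BetweenSentence")

  # word boundary: space then a letter, no sentence punctuation
  ev5 <- press(c("a", "SPACE", "b"), c(0, 100, 250))
  expect_equal(extract_pauses(ev5)$context, c("WithinWord", "BetweenWord")[-1])

  # paragraph boundary: interval spanning ENTER
  ev6 <- press(c("a", ".", "ENTER", "b"), c(0, 100, 200, 400))
  p6 <- extract_pauses(ev6)
  expect_equal(p6$context[p6$latency_ms == 200], "BetweenParagraph")
})

test_that("the worked two-word trace parses as planted", {
  # typing "ab cd" with all latencies 100 ms:
  # 2 WithinWord pauses and 1 BetweenWord pause of 100 ms each
  ev <- press(c("a", "b", "SPACE", "c", "d"), seq(0, 400, by = 100))
  p <- extract_pauses(ev)
  expect_equal(sum(p$context == "WithinWord"), 2L)
  expect_equal(sum(p$context == "BetweenWord"), 1L)
  expect_equal(nrow(p), 3L)
  expect_true(all(p$latency_ms == 100))
})

test_that("stream guards: monotonicity, empties, zero latencies", {
  expect_equal(nrow(extract_pauses(press("a", 0))), 0L)
  bad <- press(c("a", "b", "c"), c(0, 500, 300))
  expect_error(extract_pauses(bad), "line 3")
  # same-timestamp interval dropped as a logging artifact
  ev <- press(c("a", "b", "c"), c(0, 100, 100))
  expect_equal(nrow(extract_pauses(ev)), 1L)
})

test_that("select_context filters and partitions", {
  p <- data.frame(
    context = c("WithinWord", "BetweenWord", "WithinWord", "Edit"),
    latency_ms = c(100, 200, 300, 400), stringsAsFactors = FALSE)
  expect_equal(select_context(p, "WithinWord"), c(100, 300))
  expect_equal(select_context(p[0, ], "Edit"), numeric(0))
  expect_error(select_context(p, "Typo"), "unknown context")
  # per-context selections partition the table
  all_sel <- unlist(lapply(PAUSE_CONTEXTS, select_context, pauses = p))
  expect_setequal(all_sel, p$latency_ms)
  counts <- vapply(PAUSE_CONTEXTS, function(cx)
    length(select_context(p, cx)), integer(1))
  expect_equal(sum(counts), nrow(p))
})

test_that("generator and parser round-trip exactly", {
  plan <- plan_from_text("ab cd. ef")
  log <- generate_keystroke_log(plan, seed = 1)
  parsed <- extract_pauses(log$events)
  expect_equal(parsed$context, log$planted$context)
  expect_equal(parsed$latency_ms, log$planted$latency_ms)

  # single character: no intervals at all
  log1 <- generate_keystroke_log(plan_from_text("x"), seed = 2)
  expect_equal(nrow(log1$planted), 0L)
  expect_equal(nrow(extract_pauses(log1$events)), 0L)

  # determinism: identical plan + seed gives identical streams
  l1 <- generate_keystroke_log(plan, seed = 33)
  l2 <- generate_keystroke_log(plan, seed = 33)
  expect_identical(l1$events, l2$events)

  expect_error(generate_keystroke_log(character(0)), "non-empty")
})

test_that("random plans round-trip across all boundary classes", {
  seen <- character(0)
  for (r in 1:40) {
    plan <- random_text_plan(n_words = 10, seed = 4000 + r)
    log <- generate_keystroke_log(plan, seed = 8000 + r)
    parsed <- extract_pauses(log$events)
    expect_identical(parsed$context, log$planted$context)
    expect_identical(parsed$latency_ms, as.numeric(log$planted$latency_ms))
    seen <- union(seen, parsed$context)
  }
  # the random plans exercise every one of the eight contexts
  expect_setequal(seen, PAUSE_CONTEXTS)
})

test_that("keystroke logs survive a CSV round trip", {
  log <- generate_keystroke_log(plan_from_text("hi there."), seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_keystroke_log(log$events, path)
  back <- read_keystroke_log(path)
  expect_equal(back$timestamp_ms, log$events$timestamp_ms)
  expect_equal(back$key, log$events$key)
  expect_equal(extract_pauses(back), extract_pauses(log$events))
})
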