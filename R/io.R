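#' Write / read a pause corpus as JSONL
#'
#' One essay per line: `id`, `strand1`, `strand3`, `n_chars_typed`,
#' `low_effort`, and `pauses` as an array of `[context, latency_ms]`
#' pairs. The truth ledger (when present) is written separately with
#' [write_truth_ledger()].
#'
#' @param corpus a `"pause_corpus"` or list of essay records.
#' @param path output file path.
#' @return `read_corpus_jsonl()` returns a `"pause_corpus"` (without
#'   truth ledger).
#' @export
write_corpus_jsonl <- function(corpus, path) {
  essays <- corpus_essays(corpus)
  lines <- vapply(essays, function(e) {
    jsonlite::toJSON(list(
      id = e$essay_id, strand1 = e$strand1, strand3 = e$strand3,
      n_chars_typed = e$n_chars_typed,
      low_effort = isTRUE(e$low_effort),
      pauses = if (nrow(e$pauses)) Map(function(c, l) list(c, l),
                                       e$pauses$context,
                                       e$pauses$latency_ms) else list()),
      auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_corpus_jsonl
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path)
  essays <- lapply(lines, function(ln) {
    x <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    pauses <- if (length(x$pauses)) {
      data.frame(
        context = unname(vapply(x$pauses,
                                function(p) as.character(p[[1L]]),
                                character(1))),
        latency_ms = unname(vapply(x$pauses,
                                   function(p) as.numeric(p[[2L]]),
                                   numeric(1))),
        stringsAsFactors = FALSE)
    } else data.frame(context = character(0), latency_ms = numeric(0))
    list(essay_id = x$id, pauses = pauses,
         n_chars_typed = x$n_chars_typed,
         strand1 = x$strand1, strand3 = x$strand3,
         low_effort = isTRUE(x$low_effort))
  })
  structure(list(essays = essays, truth = NULL, config = NULL),
            class = "pause_corpus")
}

#' Write / read the truth ledger
#'
#' The ledger is a CSV keyed by `essay_id` with the generating parameters
#' of each synthetic essay (true mixing proportions, means, SDs, latent
#' ability, realized counts). It is the oracle for recovery tests.
#'
#' @param truth data frame (`corpus$truth`).
#' @param path file path.
#' @export
write_truth_ledger <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_ledger
#' @export
read_truth_ledger <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Serialize per-essay mixture fits to JSON
#'
#' One record per essay and component count: `essay_id`, `K`, `mu`,
#' `sigma`, `pi`, `loglik`, `converged`, `estimable`, `n_iter`, `n_obs`.
#'
#' @param results list of per-essay [fit_k_range()] results (named by
#'   essay id).
#' @param path output path.
#' @export
write_fits_json <- function(results, path) {
  recs <- list()
  for (id in names(results)) {
    for (f in results[[id]]$fits) {
      recs[[length(recs) + 1L]] <- list(
        essay_id = id, K = f$K,
        mu = if (f$estimable) f$spec$mu else NULL,
        sigma = if (f$estimable) f$spec$sigma else NULL,
        pi = if (f$estimable) f$spec$pi else NULL,
        loglik = if (f$estimable) f$loglik else NA,
        converged = f$converged, estimable = f$estimable,
        n_iter = f$n_iter, n_obs = f$n_obs)
    }
  }
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
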