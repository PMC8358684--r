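#' Fit the mixture-model battery to every essay of a corpus
#'
#' For each essay, extracts the latencies of the analysed context and fits
#' a lognormal mixture for every K in `K_range` (see [fit_k_range()]).
#' Per-essay non-convergence is recorded, never fatal.
#'
#' @param corpus a `"pause_corpus"` or list of essay records.
#' @param context linguistic context to analyse (default `"WithinWord"`).
#' @param K_range component counts to fit, default `2:5`.
#' @param seed integer seed; one child seed per essay drives the EM
#'   restart jitter.
#' @param ... further arguments passed to [fit_lnmix()].
#' @return named list (by essay id) of [fit_k_range()] results.
#' @export
analyze_corpus <- function(corpus, context = "WithinWord", K_range = 2:5,
                           seed = 1L, ...) {
  essays <- corpus_essays(corpus)
  seeds <- split_seed(seed, length(essays))
  out <- vector("list", length(essays))
  ids <- vapply(essays, `[[`, character(1), "essay_id")
  for (i in seq_along(essays)) {
    lat <- select_context(essays[[i]]$pauses, context)
    out[[i]] <- fit_k_range(lat, K_range = K_range, essay_id = ids[i],
                            seed = seeds[i], ...)
  }
  names(out) <- ids
  out
}

#' Per-essay model-selection table
#'
#' Flattens the per-essay selection records into one data frame: per K the
#' log-likelihood, AIC, BIC and convergence flag, then the chosen K under
#' each criterion, their agreement, and the smallest pairwise
#' mean-distance of the K = 3 and K = 4 fits where available.
#'
#' @param results output of [analyze_corpus()].
#' @return data frame, one row per essay.
#' @export
selection_table <- function(results) {
  rows <- lapply(names(results), function(id) {
    res <- results[[id]]
    fits <- res$fits
    Ks <- as.integer(names(fits))
    N <- fits[[1L]]$n_obs
    row <- data.frame(essay_id = id, N = N, stringsAsFactors = FALSE)
    for (j in seq_along(Ks)) {
      f <- fits[[j]]
      K <- Ks[j]
      ll <- if (f$estimable) f$loglik else NA_real_
      row[[paste0("loglik_K", K)]] <- ll
      row[[paste0("AIC_K", K)]] <-
        if (is.na(ll)) NA_real_ else aic(ll, count_parameters(K))
      row[[paste0("BIC_K", K)]] <-
        if (is.na(ll)) NA_real_ else bic(ll, count_parameters(K), N)
      row[[paste0("converged_K", K)]] <- f$converged
    }
    if (!is.null(res$record)) {
      row$chosen_K_aic <- res$record$chosen_K_aic
      row$chosen_K_bic <- res$record$chosen_K_bic
      row$agreement <- res$record$agreement
    } else {
      row$chosen_K_aic <- NA_integer_
      row$chosen_K_bic <- NA_integer_
      row$agreement <- NA
    }
    for (K in intersect(c(3L, 4L), Ks)) {
      f <- fits[[as.character(K)]]
      row[[paste0("min_distance_K", K)]] <-
        if (f$estimable) min(pairwise_mean_distances(f)) else NA_real_
    }
    row
  })
  do.call(rbind, rows)
}

#' Corpus-level summary: census, selection tallies, separation
#'
#' @param results output of [analyze_corpus()].
#' @param cut_well,cut_reasonable separation cut-points (log-ms).
#' @return list with `census` (nested convergence counts), `selected`
#'   (essays favoured per K by AIC and by BIC), `n_agreement`, and
#'   `separation` (per-K essay- and pair-level percentages for K = 3, 4).
#' @export
corpus_summary <- function(results, cut_well = 1, cut_reasonable = 0.3) {
  tab <- selection_table(results)
  Ks <- as.integer(sub("^converged_K", "",
                       grep("^converged_K", names(tab), value = TRUE)))
  conv <- as.matrix(tab[paste0("converged_K", Ks)])
  colnames(conv) <- Ks
  census <- convergence_census(conv)
  sel <- list(
    aic = table(factor(tab$chosen_K_aic, levels = Ks)),
    bic = table(factor(tab$chosen_K_bic, levels = Ks)))
  separation <- list()
  for (K in intersect(c(3L, 4L), Ks)) {
    fits <- lapply(results, function(r) r$fits[[as.character(K)]])
    fits <- Filter(function(f) isTRUE(f$converged), fits)
    if (length(fits)) {
      separation[[paste0("K", K)]] <- list(
        essay = separation_summary(fits, cut_well, cut_reasonable,
                                   unit = "essay")[
                                     c("pct_well", "pct_reasonable", "n")],
        pair = separation_summary(fits, cut_well, cut_reasonable,
                                  unit = "pair")[
                                    c("pct_well", "pct_reasonable", "n")])
    }
  }
  list(census = as.list(census),
       selected = lapply(sel, function(t) as.list(stats::setNames(
         as.integer(t), paste0("K", names(t))))),
       n_agreement = sum(tab$agreement, na.rm = TRUE),
       n_essays = nrow(tab),
       separation = separation)
}

#' Parameter-by-score table at a fixed component count
#'
#' Restricts a corpus to essays whose K-component fit converged and
#' assembles the fitted parameters (`mu1..muK`, `sigma1..sigmaK`,
#' `pi1..piK`) next to the essays' strand scores -- the input to
#' [parameter_score_correlations()]. Essays without a converged K-fit are
#' dropped and counted in the `n_dropped` attribute.
#'
#' @param results output of [analyze_corpus()].
#' @param corpus the corpus the results came from (for the scores).
#' @param K component count of the analysed model (default 3).
#' @return data frame, one row per retained essay.
#' @export
corpus_parameter_table <- function(results, corpus, K = 3L) {
  essays <- corpus_essays(corpus)
  ids <- vapply(essays, `[[`, character(1), "essay_id")
  rows <- list()
  dropped <- 0L
  for (id in names(results)) {
    f <- results[[id]]$fits[[as.character(K)]]
    if (is.null(f) || !isTRUE(f$converged)) { dropped <- dropped + 1L; next }
    e <- essays[[match(id, ids)]]
    row <- as.data.frame(as.list(coef(f)))
    row$essay_id <- id
    row$strand1 <- e$strand1
    row$strand3 <- e$strand3
    rows[[length(rows) + 1L]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(essay_id = character(0))
  attr(out, "K") <- K
  attr(out, "n_dropped") <- dropped
  out
}

#' Run the full pause-modeling pipeline
#'
#' Orchestrates synthetic generation (or loading), cleaning, per-essay
#' mixture fitting, model selection, separation screening and the
#' parameter-score correlation analysis, writing one artifact per stage
#' plus a manifest with content checksums. Two runs with the same config
#' and seed produce identical artifacts.
#'
#' @param config a list (or path to a YAML/JSON file readable by
#'   [read_run_config()]) with fields: `mode` (`"synthetic"`,
#'   `"pause-table"` or `"keystroke-log"`), `corpus` (list of
#'   [corpus_config()] arguments, synthetic mode), `input` (corpus JSONL
#'   or keystroke CSV path, other modes), `scores` (CSV with `essay_id`,
#'   `strand1`, `strand3`, `n_chars_typed`; keystroke mode), `context`,
#'   `K_range`, `table_K`, `em` (list of [fit_lnmix()] settings),
#'   `cleaning` (list: `min_events`, `score_rule`), `separation` (list:
#'   `cut_well`, `cut_reasonable`), `out_dir`, `seed`.
#' @return the run report (invisibly the same list written to the
#'   manifest): paths, cleaning report, corpus summary, correlation table.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- pipeline_defaults(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  corpus <- switch(
    cfg$mode,
    "synthetic" = {
      cc <- do.call(corpus_config,
                    utils::modifyList(cfg$corpus, list(seed = cfg$seed)))
      generate_corpus(cc)
    },
    "pause-table" = read_corpus_jsonl(cfg$input),
    "keystroke-log" = corpus_from_keystrokes(cfg$input, cfg$scores),
    stop("unknown pipeline mode: ", cfg$mode, call. = FALSE))
  if (!length(corpus_essays(corpus)))
    stop_pipeline("empty input corpus", "input")

  if (inherits(corpus, "pause_corpus") && is.data.frame(corpus$truth) &&
      nrow(corpus$truth))
    write_truth_ledger(corpus$truth,
                       file.path(cfg$out_dir, "truth_ledger.csv"))

  cl <- filter_essays(corpus, min_events = cfg$cleaning$min_events,
                      score_rule = cfg$cleaning$score_rule)
  jsonlite::write_json(cl$report,
                       file.path(cfg$out_dir, "cleaning_report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  if (!length(corpus_essays(cl$kept)))
    stop_pipeline("no essays left after cleaning", "cleaning")

  results <- do.call(analyze_corpus,
                     c(list(corpus = cl$kept, context = cfg$context,
                            K_range = cfg$K_range, seed = cfg$seed),
                       cfg$em))
  write_fits_json(results, file.path(cfg$out_dir, "fits.json"))

  tab <- selection_table(results)
  utils::write.csv(tab, file.path(cfg$out_dir, "selection_table.csv"),
                   row.names = FALSE)
  summ <- corpus_summary(results, cut_well = cfg$separation$cut_well,
                         cut_reasonable = cfg$separation$cut_reasonable)
  jsonlite::write_json(summ,
                       file.path(cfg$out_dir, "corpus_summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")

  ptab <- corpus_parameter_table(results, cl$kept, K = cfg$table_K)
  cors <- if (nrow(ptab) >= 4L)
    parameter_score_correlations(
      ptab[setdiff(names(ptab), "essay_id")]) else NULL
  if (!is.null(cors))
    utils::write.csv(cors,
                     file.path(cfg$out_dir, "correlation_table.csv"),
                     row.names = FALSE)

  artifacts <- c("cleaning_report.json", "fits.json",
                 "selection_table.csv", "corpus_summary.json",
                 if (!is.null(cors)) "correlation_table.csv")
  manifest <- list(
    package = "pausemix",
    version = as.character(utils::packageVersion("pausemix")),
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    artifacts = as.list(stats::setNames(
      unname(tools::md5sum(file.path(cfg$out_dir, artifacts))),
      artifacts)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(manifest = manifest, cleaning = cl$report,
                 summary = summ, correlations = cors,
                 out_dir = cfg$out_dir))
}

pipeline_defaults <- function(config) {
  def <- list(mode = "synthetic", corpus = list(), input = NULL,
              scores = NULL, context = "WithinWord", K_range = 2:5,
              table_K = 3L,
              em = list(n_restarts = 3L),
              cleaning = list(min_events = 30L, score_rule = "both"),
              separation = list(cut_well = 1, cut_reasonable = 0.3),
              out_dir = "pausemix_run", seed = 1L)
  cfg <- utils::modifyList(def, config)
  cfg$K_range <- as.integer(cfg$K_range)
  if (any(cfg$K_range < 1L) || any(cfg$K_range > 10L))
    stop_pipeline("K_range must lie within 1..10", "config")
  if (!(cfg$context %in% PAUSE_CONTEXTS))
    stop_pipeline(paste("invalid context:", cfg$context), "config")
  cfg
}

stop_pipeline <- function(msg, stage) {
  cond <- structure(
    class = c("pausemix_pipeline_error", "error", "condition"),
    list(message = paste0("[", stage, "] ", msg), call = sys.call(-1),
         stage = stage))
  stop(cond)
}

config_hash <- function(cfg) {
  cfg$out_dir <- NULL  # analysis settings only, not where they land
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, force = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

# build essay records from a multi-essay keystroke CSV plus a scores CSV
corpus_from_keystrokes <- function(log_path, scores_path) {
  if (is.null(log_path) || is.null(scores_path))
    stop_pipeline("keystroke-log mode needs 'input' and 'scores' paths",
                  "input")
  ev <- read_keystroke_log(log_path)
  if (!("essay_id" %in% names(ev))) ev$essay_id <- "essay0001"
  scores <- utils::read.csv(scores_path, stringsAsFactors = FALSE)
  essays <- lapply(split(ev, ev$essay_id), function(e) {
    e <- e[order(e$timestamp_ms), ]
    pauses <- extract_pauses(e)
    sc <- scores[match(e$essay_id[1L], scores$essay_id), ]
    if (!nrow(sc) || anyNA(sc$strand1) || anyNA(sc$strand3))
      stop_pipeline(paste("no scores for essay", e$essay_id[1L]),
                    "input")
    n_chars <- if ("n_chars_typed" %in% names(sc)) sc$n_chars_typed else
      sum(e$action == "press" & !(e$key %in% "BACKSPACE"))
    list(essay_id = e$essay_id[1L], pauses = pauses,
         n_chars_typed = n_chars, strand1 = sc$strand1,
         strand3 = sc$strand3, low_effort = FALSE)
  })
  structure(list(essays = unname(essays), truth = NULL, config = NULL),
            class = "pause_corpus")
}

#' Read a pipeline configuration file
#'
#' YAML (requires the yaml package) or JSON, mirroring the `config`
#' argument of [run_pipeline()].
#'
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package",
           call. = FALSE)
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml, .yml or .json", call. = FALSE)
  }
}
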