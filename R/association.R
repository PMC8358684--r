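#' Pearson correlation with a Fisher-z confidence interval
#'
#' Sample Pearson correlation plus the `1 - alpha` confidence interval
#' obtained by transforming to `atanh(r)`, using the normal quantile with
#' standard error `1/sqrt(n - 3)`, and back-transforming.
#'
#' @param x,y numeric vectors of equal length, `n >= 4`, both
#'   non-constant.
#' @param alpha two-sided error rate (default 0.05 for a 95% CI).
#' @return named numeric vector `c(r, lower, upper)`.
#' @examples
#' pearson_ci(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
#' @export
pearson_ci <- function(x, y, alpha = 0.05) {
  n <- length(x)
  if (length(y) != n) stop("'x' and 'y' lengths differ", call. = FALSE)
  if (n < 4L) stop("need at least 4 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input", call. = FALSE)
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    ci <- c(r, r)
  } else {
    z <- atanh(r)
    hw <- stats::qnorm(1 - alpha / 2) / sqrt(n - 3)
    ci <- tanh(c(z - hw, z + hw))
  }
  c(r = r, lower = ci[1L], upper = ci[2L])
}

#' Correlations between mixture parameters and strand scores
#'
#' For every fitted mixture parameter column (`mu1..muK`, `sigma1..sigmaK`,
#' `pi1..piK`) computes the Pearson correlation with each strand score,
#' with Fisher-z confidence intervals and a significance flag (CI excludes
#' zero). No multiplicity correction is applied; the flags are per-cell.
#'
#' @param table data frame with one row per essay: the parameter columns
#'   plus `strand1` and `strand3` (see [corpus_parameter_table()]).
#' @param alpha two-sided error rate for the intervals.
#' @return data frame with columns `parameter`, and per strand `r`,
#'   `lower`, `upper`, `significant`.
#' @export
parameter_score_correlations <- function(table, alpha = 0.05) {
  stopifnot(is.data.frame(table))
  scores <- intersect(c("strand1", "strand3"), names(table))
  if (!length(scores))
    stop("table has no strand score columns", call. = FALSE)
  params <- setdiff(names(table), c(scores, "essay_id", "N"))
  if (!length(params))
    stop("table has no parameter columns", call. = FALSE)
  if (nrow(table) < 4L)
    stop("need at least 4 essays", call. = FALSE)
  if (anyNA(table[c(params, scores)]))
    stop("missing values in analyzed rows", call. = FALSE)
  rows <- lapply(params, function(pm) {
    out <- data.frame(parameter = pm, stringsAsFactors = FALSE)
    for (sc in scores) {
      ci <- pearson_ci(table[[pm]], table[[sc]], alpha = alpha)
      out[[paste0("r_", sc)]] <- unname(ci["r"])
      out[[paste0("lower_", sc)]] <- unname(ci["lower"])
      out[[paste0("upper_", sc)]] <- unname(ci["upper"])
      out[[paste0("significant_", sc)]] <-
        ci["lower"] > 0 || ci["upper"] < 0
    }
    out
  })
  res <- do.call(rbind, rows)
  attr(res, "alpha") <- alpha
  attr(res, "note") <- "no multiplicity correction applied"
  res
}

#' Per-score-level spread of a fitted parameter
#'
#' Groups essays by an integer score column and reports, for each level,
#' the essay count, interquartile range and standard deviation of the
#' chosen parameter. This turns the funnel pattern -- wider spread of the
#' low-component mixing proportion among low-scoring essays -- into a
#' testable statistic.
#'
#' @param table data frame as in [parameter_score_correlations()].
#' @param parameter name of the parameter column (e.g. `"pi1"`).
#' @param score_column `"strand1"` or `"strand3"`.
#' @return data frame with columns `score`, `n`, `iqr`, `sd` (NA where a
#'   level has a single essay).
#' @export
score_band_dispersion <- function(table, parameter,
                                  score_column = "strand1") {
  stopifnot(is.data.frame(table), parameter %in% names(table),
            score_column %in% names(table))
  sc <- table[[score_column]]
  levels <- sort(unique(sc))
  if (length(levels) < 2L)
    stop("need at least 2 score levels", call. = FALSE)
  out <- lapply(levels, function(l) {
    v <- table[[parameter]][sc == l]
    data.frame(score = l, n = length(v),
               iqr = if (length(v) > 1L) stats::IQR(v) else NA_real_,
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_)
  })
  do.call(rbind, out)
}
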