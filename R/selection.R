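#' Number of free parameters of a K-component lognormal mixture
#'
#' Each component contributes a mean and an SD; the simplex constraint on
#' the mixing proportions leaves `K - 1` free weights, so the count is
#' `3K - 1` (and 2 for a single component).
#'
#' @param K component count, `K >= 1`.
#' @return integer parameter count.
#' @examples
#' count_parameters(2)  # 5
#' count_parameters(5)  # 14
#' @export
count_parameters <- function(K) {
  if (any(!is.numeric(K)) || any(K < 1) || any(K != floor(K)))
    stop("'K' must be a positive integer", call. = FALSE)
  as.integer(3 * K - 1)
}

#' Akaike information criterion
#'
#' `AIC = -2 * loglik + 2 * p`; lower is better.
#'
#' @param loglik log-likelihood of the fitted model.
#' @param p number of free parameters.
#' @export
aic <- function(loglik, p) {
  if (any(!is.finite(loglik))) stop("'loglik' must be finite", call. = FALSE)
  if (any(p < 0)) stop("'p' must be nonnegative", call. = FALSE)
  -2 * loglik + 2 * p
}

#' Bayesian information criterion
#'
#' `BIC = -2 * loglik + p * log(N)` with `N` the number of pause events the
#' model was fit to; natural logarithm, lower is better.
#'
#' @param loglik log-likelihood of the fitted model.
#' @param p number of free parameters.
#' @param N sample size, `N >= 1`.
#' @export
bic <- function(loglik, p, N) {
  if (any(!is.finite(loglik))) stop("'loglik' must be finite", call. = FALSE)
  if (any(N < 1)) stop("'N' must be >= 1", call. = FALSE)
  -2 * loglik + p * log(N)
}

#' Fit a range of component counts to one essay's latencies
#'
#' Convenience wrapper fitting [fit_lnmix()] for each `K` in `K_range` and
#' assembling the per-essay [select_model()] record.
#'
#' @param durations positive pause latencies (ms).
#' @param K_range integer vector of component counts, default `2:5`.
#' @param essay_id optional identifier carried into the record.
#' @param ... passed to [fit_lnmix()] (tolerances, restarts, seed, ...).
#' @return list with `fits` (named by K) and `record` (the
#'   [select_model()] result, or `NULL` when no fit converged).
#' @export
fit_k_range <- function(durations, K_range = 2:5, essay_id = NA_character_,
                        ...) {
  fits <- lapply(K_range, function(K) fit_lnmix(durations, K, ...))
  names(fits) <- as.character(K_range)
  rec <- tryCatch(select_model(fits, N = length(durations),
                               essay_id = essay_id),
                  pausemix_no_model = function(e) NULL)
  list(fits = fits, record = rec)
}

#' Select the number of components by AIC and BIC
#'
#' Given per-K fits of the same data, computes AIC and BIC for every fit
#' and picks, separately for each criterion, the converged fit with the
#' lowest value; ties go to the smaller K. Whether the two criteria agree
#' is recorded rather than assumed.
#'
#' @param fits named list of `"lnmix"` fits (names = K).
#' @param N number of pause events the fits used.
#' @param essay_id optional identifier.
#' @return a one-row data frame (class `"selection_record"` attributes
#'   carry the per-K table): columns `essay_id`, `N`, per-K `loglik_K`,
#'   `AIC_K`, `BIC_K`, `converged_K`, then `chosen_K_aic`, `chosen_K_bic`,
#'   `agreement`.
#' @export
select_model <- function(fits, N, essay_id = NA_character_) {
  stopifnot(length(fits) >= 1L)
  Ks <- as.integer(names(fits))
  if (any(is.na(Ks)))
    stop("select_model: 'fits' must be named by their component count",
         call. = FALSE)
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  ll <- vapply(fits, function(f) if (f$estimable) f$loglik else NA_real_,
               numeric(1))
  p <- count_parameters(Ks)
  aics <- ifelse(is.na(ll), NA_real_, -2 * ll + 2 * p)
  bics <- ifelse(is.na(ll), NA_real_, -2 * ll + p * log(N))
  if (!any(conv)) {
    cond <- structure(class = c("pausemix_no_model", "error", "condition"),
                      list(message = "no converged fit to select from",
                           call = sys.call()))
    stop(cond)
  }
  pick <- function(crit) {
    cand <- which(conv)
    cand <- cand[order(crit[cand], Ks[cand])]  # min criterion, ties -> small K
    Ks[cand[1L]]
  }
  k_aic <- pick(aics)
  k_bic <- pick(bics)
  out <- data.frame(essay_id = essay_id, N = N,
                    chosen_K_aic = k_aic, chosen_K_bic = k_bic,
                    agreement = k_aic == k_bic,
                    stringsAsFactors = FALSE)
  per_k <- data.frame(K = Ks, p = p, loglik = ll, AIC = aics, BIC = bics,
                      converged = conv, row.names = NULL)
  attr(out, "per_k") <- per_k
  class(out) <- c("selection_record", class(out))
  out
}

#' Pairwise distances between ordered component means
#'
#' For an ordered spec returns `|mu_i - mu_j|` for every pair `i < j`, in
#' the order (1,2), (1,3), ..., (K-1,K): three quantities for K = 3, six
#' for K = 4. An empty vector for K < 2.
#'
#' @param spec an ordered [mixture_spec()] or an `"lnmix"` fit.
#' @return numeric vector of length `K(K-1)/2`, named `"i-j"`.
#' @export
pairwise_mean_distances <- function(spec) {
  if (inherits(spec, "lnmix")) spec <- spec$spec
  stopifnot(inherits(spec, "lnmix_spec"))
  K <- spec$K
  if (K < 2L) return(numeric(0))
  pairs <- utils::combn(K, 2L)
  d <- abs(spec$mu[pairs[2L, ]] - spec$mu[pairs[1L, ]])
  names(d) <- paste0(pairs[1L, ], "-", pairs[2L, ])
  d
}

#' Component-separation screen across essays
#'
#' An essay's fit counts as *well separated* when every pairwise distance
#' between its component means is at least `cut_well` (default 1 log-ms)
#' and *reasonably separated* when every distance is at least
#' `cut_reasonable` (default 0.3); both boundaries are inclusive. The
#' essay-level reading (all pairs must clear the cut) is the primary one;
#' `unit = "pair"` instead reports the percentage of component pairs that
#' clear each cut, the alternative reading of "percentage of separated
#' cases".
#'
#' @param fits list of `"lnmix"` fits, all with the same K >= 2.
#' @param cut_well distance threshold for "well separated".
#' @param cut_reasonable distance threshold for "reasonably separated";
#'   must satisfy `cut_well > cut_reasonable > 0`.
#' @param unit `"essay"` (default) or `"pair"`.
#' @return list with `pct_well`, `pct_reasonable` (percentages 0-100),
#'   `unit`, `n`, and the distance matrix used.
#' @export
separation_summary <- function(fits, cut_well = 1, cut_reasonable = 0.3,
                               unit = c("essay", "pair")) {
  unit <- match.arg(unit)
  if (!length(fits))
    stop("separation_summary: empty input", call. = FALSE)
  if (!(cut_well > cut_reasonable && cut_reasonable > 0))
    stop("need cut_well > cut_reasonable > 0", call. = FALSE)
  Ks <- vapply(fits, function(f) f$K, integer(1))
  if (length(unique(Ks)) != 1L || Ks[1L] < 2L)
    stop("all fits must share the same K >= 2", call. = FALSE)
  dmat <- t(vapply(fits, pairwise_mean_distances,
                   numeric(Ks[1L] * (Ks[1L] - 1L) / 2L)))
  if (unit == "essay") {
    well <- apply(dmat >= cut_well, 1L, all)
    reas <- apply(dmat >= cut_reasonable, 1L, all)
    n <- nrow(dmat)
  } else {
    well <- dmat >= cut_well
    reas <- dmat >= cut_reasonable
    n <- length(dmat)
  }
  list(pct_well = 100 * mean(well), pct_reasonable = 100 * mean(reas),
       unit = unit, n = n, distances = dmat,
       cut_well = cut_well, cut_reasonable = cut_reasonable)
}

#' Nested convergence census across a corpus
#'
#' Counts how many essays converged to the 2-component model, to both the
#' 2- and 3-component models, and so on cumulatively up to the largest K:
#' a non-increasing sequence by construction.
#'
#' @param converged logical matrix or data frame, one row per essay, one
#'   column per K (ordered ascending, e.g. K = 2..5).
#' @return named integer vector of nested counts.
#' @export
convergence_census <- function(converged) {
  converged <- as.matrix(converged)
  if (nrow(converged) == 0L) {
    out <- integer(ncol(converged))
  } else {
    cum <- t(apply(converged, 1L, cumprod))
    if (ncol(converged) == 1L) cum <- matrix(cum, ncol = 1L)
    out <- as.integer(colSums(cum))
  }
  ks <- colnames(converged)
  if (is.null(ks)) ks <- as.character(seq_len(ncol(converged)) + 1L)
  names(out) <- vapply(seq_along(ks), function(j)
    paste0("K", paste(ks[seq_len(j)], collapse = ",")), character(1))
  out
}
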