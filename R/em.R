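#' Natural-log transform of pause durations
#'
#' Pause latencies are modeled as lognormal, so all estimation happens on
#' `x = log(y)`. Durations must be strictly positive.
#'
#' @param durations numeric vector of pause durations in milliseconds.
#' @return numeric vector `log(durations)`.
#' @export
log_transform <- function(durations) {
  if (length(durations) && (any(!is.finite(durations)) ||
                            any(durations <= 0))) {
    bad <- which(!is.finite(durations) | durations <= 0)
    stop("log_transform: nonpositive or non-finite durations at indices ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) ", ...", call. = FALSE)
  }
  log(durations)
}

#' E-step: posterior component responsibilities
#'
#' Computes the n-by-K matrix of posterior membership probabilities
#' `P(z = k | x_i, theta)`, each entry proportional to
#' `pi_k * dnorm(x_i, mu_k, sigma_k)` with rows normalized, together with
#' the observed-data log-likelihood.
#'
#' @param x numeric vector of log-scale observations.
#' @param spec an [mixture_spec()] with positive `sigma`.
#' @return list with `resp` (n-by-K matrix, rows summing to 1) and
#'   `loglik` (scalar).
#' @export
e_step <- function(x, spec) {
  check_spec_positive_sigma(spec)
  n <- length(x)
  if (n < 1L) stop("e_step: need at least one observation", call. = FALSE)
  lp <- vapply(seq_len(spec$K), function(k) {
    stats::dnorm(x, spec$mu[k], spec$sigma[k], log = TRUE) + log(spec$pi[k])
  }, numeric(n))
  lp <- matrix(lp, nrow = n)
  m <- apply(lp, 1L, max)
  if (any(!is.finite(m)))
    stop("e_step: zero mixture density at some observation (degenerate fit)",
         call. = FALSE)
  lse <- m + log(rowSums(exp(lp - m)))
  list(resp = exp(lp - lse), loglik = sum(lse))
}

#' M-step: weighted-moment parameter updates
#'
#' Given responsibilities, updates the mixture parameters by their
#' complete-data maximum-likelihood expressions: `pi_k` is the column mean,
#' `mu_k` the responsibility-weighted mean of `x`, and `sigma_k` the square
#' root of the responsibility-weighted variance about `mu_k`, floored at
#' `sigma_floor`.
#'
#' @param x numeric vector of log-scale observations.
#' @param resp n-by-K responsibility matrix with rows summing to 1.
#' @param sigma_floor lower bound for the updated standard deviations.
#' @return an [mixture_spec()] with the updated parameters.
#' @export
m_step <- function(x, resp, sigma_floor = 1e-3) {
  resp <- as.matrix(resp)
  n <- length(x)
  if (nrow(resp) != n)
    stop("m_step: 'resp' must have one row per observation", call. = FALSE)
  if (any(abs(rowSums(resp) - 1) > 1e-8))
    stop("m_step: responsibility rows must sum to 1", call. = FALSE)
  nk <- colSums(resp)
  mu <- colSums(resp * x) / nk
  sigma <- sqrt(colSums(resp * outer(x, mu, "-")^2) / nk)
  mixture_spec(mu = mu, sigma = pmax(sigma, sigma_floor), pi = nk / n)
}

# First-restart initializer: one-dimensional k-means seeded at the K
# evenly spaced data quantiles (deterministic), with per-cluster moments
# as starting values. k-means adapts the cluster sizes to skewed mixing
# proportions, which keeps the subsequent EM run in the basin of the
# component-aligned solution far more reliably than equal-count slicing.
# Falls back to quantile slicing when k-means degenerates (ties etc.).
em_init_kmeans <- function(x, K, sigma_floor = 1e-3) {
  if (K == 1L)
    return(list(mu = mean(x), sigma = max(stats::sd(x), sigma_floor),
                pi = 1))
  centers <- stats::quantile(x, (2 * seq_len(K) - 1) / (2 * K),
                             names = FALSE)
  if (anyDuplicated(centers)) return(em_init(x, K, 0, sigma_floor))
  km <- tryCatch(
    suppressWarnings(stats::kmeans(x, centers = matrix(centers),
                                   iter.max = 50L)),
    error = function(e) NULL)
  if (is.null(km) || any(km$size == 0L))
    return(em_init(x, K, 0, sigma_floor))
  o <- order(km$centers)
  sigma <- vapply(seq_len(K), function(k) {
    stats::sd(x[km$cluster == k])
  }, numeric(1))[o]
  sigma[!is.finite(sigma)] <- sigma_floor
  list(mu = as.numeric(km$centers)[o],
       sigma = pmax(sigma, sigma_floor),
       pi = (km$size / length(x))[o])
}

# k-quantile slicing init: cut sorted log data into K contiguous blocks;
# per-block mean/SD/frequency seed the run. Restarts jitter the block
# boundaries with seeded uniform noise.
em_init <- function(x, K, jitter = 0, sigma_floor = 1e-3) {
  xs <- sort(x)
  n <- length(xs)
  cuts <- seq(0, 1, length.out = K + 1L)
  if (jitter > 0 && K > 1L) {
    inner <- cuts[2:K] + stats::runif(K - 1L, -jitter, jitter)
    cuts <- c(0, sort(pmin(pmax(inner, 0.02), 0.98)), 1)
  }
  idx <- pmin(pmax(1L, ceiling(cuts * n)), n)
  mu <- sigma <- pi <- numeric(K)
  for (k in seq_len(K)) {
    lo <- if (k == 1L) 1L else idx[k] + 1L
    hi <- idx[k + 1L]
    if (hi < lo) { lo <- hi <- max(1L, idx[k + 1L]) }
    blk <- xs[lo:hi]
    mu[k] <- mean(blk)
    sigma[k] <- max(stats::sd(blk), sigma_floor, na.rm = TRUE)
    pi[k] <- length(blk) / n
  }
  sigma[!is.finite(sigma)] <- sigma_floor
  pi <- pi / sum(pi)
  # guarantee distinct starting means even for blocky data
  if (anyDuplicated(mu)) mu <- mu + seq_len(K) * 1e-6
  list(mu = mu, sigma = sigma, pi = pi)
}

#' Fit a K-component lognormal mixture by EM
#'
#' The central fitting routine. Durations are log-transformed; a normal
#' mixture is then estimated on the log scale by expectation-maximization
#' (equivalently, a lognormal mixture on the raw scale). The primary EM
#' run starts from a deterministic one-dimensional k-means partition
#' (centers seeded at evenly spaced data quantiles); when that run
#' converges cleanly it *is* the estimate. Location-scale mixture
#' likelihoods are unbounded, with near-tied spurious local maxima, so
#' the statistically meaningful root is the well-initialized local
#' maximum rather than the highest likelihood any restart can reach (see
#' the methods vignette). Up to `n_restarts - 1` quantile-slice restarts
#' with seeded boundary jitter serve as a fallback when the primary run
#' fails to converge: the best converged restart is taken, or the
#' highest-likelihood run if none converges.
#'
#' A fit is declared converged when the relative log-likelihood improvement
#' fell below `tol` before `max_iter` iterations and no component ended at
#' the `sigma_floor` or below the `weight_floor` (degeneracy guards against
#' the unbounded-likelihood pathology of location-scale mixtures). Fewer
#' than `K` distinct log-values makes the model non-estimable; the returned
#' fit is then flagged `converged = FALSE`, `estimable = FALSE` and counts
#' towards a corpus's non-convergence census.
#'
#' @param durations positive pause durations in milliseconds.
#' @param K number of mixture components.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per restart.
#' @param n_restarts maximum number of EM runs (primary + fallback
#'   restarts).
#' @param sigma_floor lower bound on component SDs (log-ms).
#' @param weight_floor minimum component weight for a converged fit;
#'   default `1/n`.
#' @param seed optional integer seed controlling the restart jitter.
#' @return An object of class `"lnmix"`: a list with `spec` (ordered by
#'   increasing `mu`), `loglik`, `converged`, `estimable`, `n_iter`,
#'   `loglik_trace` (best restart), `n_obs`, `K`, and the call.
#' @examples
#' y <- sample_mixture_pauses(
#'   mixture_spec(c(4.6, 5.8, 7.0), rep(.45, 3), c(.55, .3, .15)),
#'   500, seed = 1)
#' fit <- fit_lnmix(y, K = 3, seed = 1)
#' coef(fit)
#' @export
fit_lnmix <- function(durations, K, tol = 1e-8, max_iter = 1000L,
                      n_restarts = 10L, sigma_floor = 1e-3,
                      weight_floor = NULL, seed = NULL) {
  if (!is.numeric(K) || length(K) != 1L || K < 1 || K != floor(K))
    stop("'K' must be a positive integer", call. = FALSE)
  K <- as.integer(K)
  x <- log_transform(durations)
  n <- length(x)
  if (is.null(weight_floor)) weight_floor <- 1 / max(n, 1L)

  if (length(unique(x)) < K) {
    fit <- structure(list(
      spec = NULL, K = K, loglik = NA_real_, converged = FALSE,
      estimable = FALSE, n_iter = 0L, loglik_trace = numeric(0),
      n_obs = n, seed = seed, call = match.call()), class = "lnmix")
    return(fit)
  }

  run_ok <- function(run) {
    !identical(run$status, "degenerate")
  }
  run_clean <- function(run) {
    run_ok(run) && isTRUE(run$tol_met) && !isTRUE(run$at_sigma_floor) &&
      !isTRUE(run$at_weight_floor)
  }
  with_seed(seed, {
    # primary root: deterministic k-means start; kept whenever it
    # converges cleanly (root selection, not likelihood race)
    ini <- em_init_kmeans(x, K, sigma_floor)
    best <- .em_run_cpp(x, ini$mu, ini$sigma, ini$pi, tol,
                        as.integer(max_iter), sigma_floor, weight_floor)
    if (!run_clean(best)) {
      runs <- if (run_ok(best)) list(best) else list()
      for (r in seq_len(max(n_restarts - 1L, 0L))) {
        ini <- em_init(x, K, jitter = 0.45 / K,
                       sigma_floor = sigma_floor)
        run <- .em_run_cpp(x, ini$mu, ini$sigma, ini$pi, tol,
                           as.integer(max_iter), sigma_floor,
                           weight_floor)
        if (run_ok(run)) runs <- c(runs, list(run))
      }
      if (!length(runs))
        stop("fit_lnmix: every restart collapsed to a degenerate ",
             "solution", call. = FALSE)
      clean <- Filter(run_clean, runs)
      pool <- if (length(clean)) clean else runs
      best <- pool[[which.max(vapply(pool, `[[`, numeric(1),
                                     "loglik"))]]
    }
    conv <- run_clean(best)
    fit <- structure(list(
      spec = mixture_spec(best$mu, best$sigma, best$pi),
      K = K, loglik = best$loglik, converged = conv, estimable = TRUE,
      n_iter = best$n_iter, loglik_trace = best$trace, n_obs = n,
      seed = seed, call = match.call()), class = "lnmix")
    order_components(fit)
  })
}

#' Order mixture components by increasing mean
#'
#' Resolves label switching by sorting components on `mu` (the component
#' with the smallest mean is the low-cognitive component); `sigma` and `pi`
#' are permuted consistently and the log-likelihood is unchanged. Ties keep
#' their original relative order (stable sort).
#'
#' @param fit an `"lnmix"` fit or an [mixture_spec()].
#' @return the same object with components ordered.
#' @export
order_components <- function(fit) {
  if (inherits(fit, "lnmix_spec")) {
    o <- order(fit$mu)  # stable: ties keep original index order
    return(mixture_spec(fit$mu[o], fit$sigma[o], fit$pi[o]))
  }
  stopifnot(inherits(fit, "lnmix"))
  if (!is.null(fit$spec)) fit$spec <- order_components(fit$spec)
  fit
}

#' @export
print.lnmix <- function(x, digits = 4, ...) {
  cat("Lognormal mixture fit (K =", x$K, ")\n")
  if (!x$estimable) {
    cat("  not estimable: fewer than K distinct log-durations\n")
    return(invisible(x))
  }
  print(x$spec, digits = digits)
  cat("logLik:", format(x$loglik, digits = digits + 2),
      " n:", x$n_obs,
      " iterations:", x$n_iter,
      " converged:", x$converged, "\n")
  invisible(x)
}

#' @export
summary.lnmix <- function(object, ...) {
  out <- object
  if (object$estimable) {
    out$aic <- aic(object$loglik, count_parameters(object$K))
    out$bic <- bic(object$loglik, count_parameters(object$K), object$n_obs)
    d <- pairwise_mean_distances(object$spec)
    out$min_separation <- if (length(d)) min(d) else NA_real_
  }
  class(out) <- c("summary.lnmix", "lnmix")
  out
}

#' @export
print.summary.lnmix <- function(x, digits = 4, ...) {
  print.lnmix(x, digits = digits, ...)
  if (x$estimable) {
    cat("AIC:", format(x$aic, digits = digits + 2),
        " BIC:", format(x$bic, digits = digits + 2), "\n")
    if (is.finite(x$min_separation))
      cat("smallest |mu_i - mu_j|:",
          format(x$min_separation, digits = digits), "\n")
  }
  invisible(x)
}

#' @export
coef.lnmix <- function(object, ...) {
  if (!object$estimable) return(NULL)
  s <- object$spec
  stats::setNames(
    c(s$mu, s$sigma, s$pi),
    c(paste0("mu", seq_len(s$K)), paste0("sigma", seq_len(s$K)),
      paste0("pi", seq_len(s$K))))
}

#' @export
logLik.lnmix <- function(object, ...) {
  structure(object$loglik, df = count_parameters(object$K),
            nobs = object$n_obs, class = "logLik")
}

#' Predict method for lognormal mixture fits
#'
#' @param object an `"lnmix"` fit.
#' @param newdata positive durations (ms) to evaluate at; defaults to the
#'   fitted range.
#' @param type `"logdensity"` or `"density"` of the log-latency mixture, or
#'   `"responsibility"` for the posterior membership matrix.
#' @param ... unused.
#' @export
predict.lnmix <- function(object, newdata, type = c("logdensity", "density",
                                                    "responsibility"), ...) {
  type <- match.arg(type)
  if (!object$estimable) stop("fit is not estimable", call. = FALSE)
  x <- log_transform(newdata)
  switch(type,
         logdensity = mixture_logdensity(x, object$spec),
         density = exp(mixture_logdensity(x, object$spec)),
         responsibility = e_step(x, object$spec)$resp)
}

#' @export
simulate.lnmix <- function(object, nsim = 1, seed = NULL, ...) {
  if (!object$estimable) stop("fit is not estimable", call. = FALSE)
  sample_mixture_pauses(object$spec, object$n_obs * nsim, seed = seed)
}

#' Randomized quantile residuals for a lognormal mixture fit
#'
#' Maps each observation through the fitted mixture CDF on the log scale and
#' back through the standard-normal quantile function; for a well-fitting
#' model these are approximately standard normal.
#'
#' @param object an `"lnmix"` fit.
#' @param durations durations to compute residuals for; defaults must be
#'   supplied by the caller since the fit does not store its data.
#' @param ... unused.
#' @export
residuals.lnmix <- function(object, durations, ...) {
  if (!object$estimable) stop("fit is not estimable", call. = FALSE)
  x <- log_transform(durations)
  s <- object$spec
  cdf <- rowSums(vapply(seq_len(s$K), function(k) {
    s$pi[k] * stats::pnorm(x, s$mu[k], s$sigma[k])
  }, numeric(length(x))))
  stats::qnorm(pmin(pmax(cdf, .Machine$double.eps),
                    1 - .Machine$double.eps))
}

#' @export
plot.lnmix <- function(x, durations = NULL, breaks = 40, ...) {
  if (!x$estimable) stop("fit is not estimable", call. = FALSE)
  s <- x$spec
  rng <- range(s$mu) + c(-3.5, 3.5) * max(s$sigma)
  grid <- seq(rng[1], rng[2], length.out = 400)
  dens <- exp(mixture_logdensity(grid, s))
  if (!is.null(durations)) {
    graphics::hist(log_transform(durations), breaks = breaks, freq = FALSE,
                   main = "Log pause latencies", xlab = "log latency (log-ms)",
                   border = "grey70", ...)
    graphics::lines(grid, dens, lwd = 2)
  } else {
    graphics::plot(grid, dens, type = "l", lwd = 2,
                   xlab = "log latency (log-ms)", ylab = "density",
                   main = "Fitted lognormal mixture", ...)
  }
  for (k in seq_len(s$K))
    graphics::lines(grid, s$pi[k] * stats::dnorm(grid, s$mu[k], s$sigma[k]),
                    lty = 2)
  invisible(x)
}
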