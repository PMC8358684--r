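#' Construct a K-component lognormal mixture specification
#'
#' A mixture specification holds the component parameters of a lognormal
#' mixture: on the natural-log scale each component k is Normal with mean
#' `mu[k]` (log-ms) and standard deviation `sigma[k]` (log-ms), and is drawn
#' with mixing proportion `pi[k]`. The proportions lie on the simplex.
#'
#' Degenerate components (`sigma = 0`) are admitted so that point-mass
#' mixtures can be simulated; density and fitting routines require strictly
#' positive `sigma`.
#'
#' @param mu numeric vector of component means on the log-millisecond scale.
#' @param sigma numeric vector of component standard deviations (log-ms),
#'   each `>= 0`.
#' @param pi numeric vector of mixing proportions; must be nonnegative and
#'   sum to 1 within `1e-12`.
#' @param ordered logical; if `TRUE`, additionally require `mu` to be
#'   non-decreasing (the convention used after label-switching resolution).
#'
#' @return An object of class `"lnmix_spec"`: a list with elements `K`,
#'   `mu`, `sigma`, `pi`.
#' @examples
#' mixture_spec(mu = c(4.6, 5.8, 7.0), sigma = rep(0.45, 3),
#'              pi = c(0.55, 0.30, 0.15))
#' @export
mixture_spec <- function(mu, sigma, pi, ordered = FALSE) {
  mu <- as.numeric(mu); sigma <- as.numeric(sigma); pi <- as.numeric(pi)
  K <- length(mu)
  if (K < 1L)
    stop("mixture_spec: need at least one component", call. = FALSE)
  if (length(sigma) != K || length(pi) != K)
    stop("mixture_spec: 'mu', 'sigma' and 'pi' must have equal length",
         call. = FALSE)
  if (any(!is.finite(mu)) || any(!is.finite(sigma)) || any(!is.finite(pi)))
    stop("mixture_spec: parameters must be finite", call. = FALSE)
  if (any(sigma < 0))
    stop("mixture_spec: 'sigma' must be nonnegative", call. = FALSE)
  if (any(pi < 0))
    stop("mixture_spec: mixing proportions must be nonnegative",
         call. = FALSE)
  if (abs(sum(pi) - 1) > 1e-12)
    stop("mixture_spec: mixing proportions must sum to 1 (within 1e-12), got ",
         format(sum(pi), digits = 16), call. = FALSE)
  if (ordered && is.unsorted(mu))
    stop("mixture_spec: 'mu' must be non-decreasing when ordered = TRUE",
         call. = FALSE)
  structure(list(K = K, mu = mu, sigma = sigma, pi = pi),
            class = "lnmix_spec")
}

#' @export
print.lnmix_spec <- function(x, digits = 4, ...) {
  cat("Lognormal mixture specification (K =", x$K, ")\n")
  tab <- rbind(mu = x$mu, sigma = x$sigma, pi = x$pi)
  colnames(tab) <- paste0("comp", seq_len(x$K))
  print(round(tab, digits))
  invisible(x)
}

# internal guard used by density / EM code, where sigma = 0 is not allowed
check_spec_positive_sigma <- function(spec) {
  stopifnot(inherits(spec, "lnmix_spec"))
  if (any(spec$sigma <= 0))
    stop("mixture density requires strictly positive 'sigma'", call. = FALSE)
  invisible(spec)
}

#' Mixture log-density on the log scale
#'
#' Evaluates the log of the normal-mixture density
#' `sum_k pi_k * dnorm(x, mu_k, sigma_k)` at log-scale points `x`.
#' Computed with the log-sum-exp trick so very extreme `x` do not overflow
#' or spuriously underflow to `-Inf`.
#'
#' @param x numeric vector of points on the log-millisecond scale.
#' @param spec an [mixture_spec()] with strictly positive `sigma`.
#' @return numeric vector of log-density values, same length as `x`.
#' @examples
#' spec <- mixture_spec(0, 1, 1)
#' exp(mixture_logdensity(0, spec))  # 1/sqrt(2*pi)
#' @export
mixture_logdensity <- function(x, spec) {
  check_spec_positive_sigma(spec)
  lw <- log(spec$pi)                       # -Inf for zero-weight components
  lp <- vapply(seq_len(spec$K), function(k) {
    stats::dnorm(x, spec$mu[k], spec$sigma[k], log = TRUE) + lw[k]
  }, numeric(length(x)))
  lp <- matrix(lp, nrow = length(x))
  m <- apply(lp, 1L, max)
  out <- m + log(rowSums(exp(lp - m)))
  out[!is.finite(m)] <- -Inf
  out
}

#' Sample pause durations from a lognormal mixture
#'
#' Draws component memberships with probabilities `pi_k`, then durations
#' `exp(Normal(mu_k, sigma_k))` in milliseconds. A degenerate component
#' (`sigma = 0`) yields the point mass `exp(mu)`.
#'
#' @param spec an [mixture_spec()].
#' @param n number of durations to draw (`n >= 1`).
#' @param seed optional integer seed; when supplied the draw is reproducible
#'   and the caller's RNG state is left untouched.
#' @return numeric vector of `n` strictly positive durations (ms).
#' @examples
#' spec <- mixture_spec(mu = c(4, 6), sigma = c(.5, .5), pi = c(.5, .5))
#' y <- sample_mixture_pauses(spec, 5, seed = 1)
#' @export
sample_mixture_pauses <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "lnmix_spec"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n))
    stop("'n' must be a positive integer", call. = FALSE)
  with_seed(seed, {
    z <- sample.int(spec$K, n, replace = TRUE, prob = spec$pi)
    x <- stats::rnorm(n, mean = spec$mu[z], sd = spec$sigma[z])
    exp(x)
  })
}

# Evaluate `code` under a given seed without disturbing the caller's RNG
# stream; with seed = NULL the code just runs on the current stream. Used by
# every sampling routine so corpora are reproducible element-wise from one
# integer seed.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Split one base seed into n reproducible child seeds (one per essay etc.).
# Kept below 2^31 so they are valid R integer seeds.
split_seed <- function(seed, n) {
  n <- as.integer(n)
  if (n == 0L) return(integer(0))
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}
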