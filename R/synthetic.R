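#' Configuration of a synthetic pause-event corpus
#'
#' Describes the generative model used to emulate a writing-assessment
#' corpus: per-essay pause latencies come from a K-component lognormal
#' mixture whose low-component weight is tied to a latent writing ability;
#' integer strand scores are noisy discretizations of the same ability;
#' per-essay event counts follow a (truncated) negative binomial; a fixed
#' fraction of essays is generated as low-effort (fewer than 30 events,
#' both scores 0).
#'
#' The ability -> mixing-proportion link works on the logit scale:
#' `logit(pi_1) = logit(pi_base[1]) - score_link * ability + noise`, with
#' the remaining proportions rescaled pro rata so `pi` stays on the
#' simplex for any slope. Positive `score_link` therefore gives low-ability
#' writers a larger low-cognitive proportion, inducing a negative
#' correlation between `pi_1` and the strand scores; the default slope is
#' calibrated (see [calibrate_score_link()]) so that correlation is about
#' `target_corr`.
#'
#' @param n_essays number of essays to generate.
#' @param mu,sigma,pi_base component means (log-ms), SDs and baseline
#'   mixing proportions of the true mixture; `mu` strictly increasing.
#' @param score_link nonnegative slope of the ability link (logit scale).
#' @param target_corr intended Pearson correlation between true `pi_1`
#'   and a strand score (sign and rough magnitude; metadata used by the
#'   calibration helper).
#' @param pi_noise_sd SD of essay-level logit noise on `pi_1`.
#' @param pi_noise_het heteroscedasticity coefficient: the logit-noise SD
#'   for an essay with ability `a` is `pi_noise_sd * (1 + pi_noise_het *
#'   (1 - pnorm(a)))`, so low-ability essays get the wider spread of
#'   mixing proportions; 0 (default) is homoscedastic.
#' @param score_noise_sd SD of the rater noise added to ability before
#'   discretizing into integer scores.
#' @param score_scale integer score range, default `0:5`.
#' @param events_dist list with `mu` and `size`: negative-binomial mean
#'   and dispersion of per-essay event counts, truncated at `min_events`.
#' @param min_events lower truncation for non-low-effort essays (default
#'   31, so ordinary essays always survive the cleaning rule).
#' @param max_events upper truncation of the event-count distribution.
#' @param low_effort_frac fraction of essays generated with fewer than 30
#'   events and both scores 0; `0 <= low_effort_frac < 1`.
#' @param context analysed context label attached to mixture-drawn pause
#'   events (default `"WithinWord"`).
#' @param context_other_frac fraction of each ordinary essay's events
#'   assigned to the seven other contexts (background latencies, not drawn
#'   from the essay's mixture).
#' @param seed integer seed; all corpus randomness derives from it.
#' @return an object of class `"corpus_config"` (a validated list).
#' @export
corpus_config <- function(n_essays = 1054,
                          mu = c(4.6, 5.8, 7.0),
                          sigma = c(0.45, 0.45, 0.45),
                          pi_base = c(0.55, 0.30, 0.15),
                          score_link = 0.174,
                          target_corr = -0.23,
                          pi_noise_sd = 0.55,
                          pi_noise_het = 0,
                          score_noise_sd = 0.8,
                          score_scale = 0:5,
                          events_dist = list(mu = 594, size = 2.2),
                          min_events = 31L,
                          max_events = 2500L,
                          low_effort_frac = 0.09,
                          context = "WithinWord",
                          context_other_frac = 0.15,
                          seed = 1L) {
  cfg <- list(n_essays = as.integer(n_essays), mu = as.numeric(mu),
              sigma = as.numeric(sigma), pi_base = as.numeric(pi_base),
              score_link = score_link, target_corr = target_corr,
              pi_noise_sd = pi_noise_sd, pi_noise_het = pi_noise_het,
              score_noise_sd = score_noise_sd,
              score_scale = as.integer(score_scale),
              events_dist = events_dist,
              min_events = as.integer(min_events),
              max_events = as.integer(max_events),
              low_effort_frac = low_effort_frac, context = context,
              context_other_frac = context_other_frac,
              seed = as.integer(seed))
  validate_corpus_config(cfg)
}

validate_corpus_config <- function(cfg) {
  K <- length(cfg$mu)
  if (K < 1L || K > 5L)
    stop("corpus_config: 1-5 mixture components supported", call. = FALSE)
  if (length(cfg$sigma) != K || length(cfg$pi_base) != K)
    stop("corpus_config: 'mu', 'sigma', 'pi_base' lengths differ",
         call. = FALSE)
  if (any(cfg$sigma <= 0))
    stop("corpus_config: 'sigma' must be strictly positive", call. = FALSE)
  if (K > 1L && any(diff(cfg$mu) <= 0))
    stop("corpus_config: 'mu' must be strictly increasing", call. = FALSE)
  if (any(cfg$pi_base < 0) || abs(sum(cfg$pi_base) - 1) > 1e-12)
    stop("corpus_config: 'pi_base' must be on the simplex (sum 1 within ",
         "1e-12)", call. = FALSE)
  if (cfg$low_effort_frac < 0 || cfg$low_effort_frac >= 1)
    stop("corpus_config: need 0 <= low_effort_frac < 1", call. = FALSE)
  if (cfg$n_essays < 0)
    stop("corpus_config: 'n_essays' must be nonnegative", call. = FALSE)
  if (cfg$score_link < 0)
    stop("corpus_config: 'score_link' must be nonnegative", call. = FALSE)
  if (!(cfg$context %in% PAUSE_CONTEXTS))
    stop("corpus_config: unknown context label", call. = FALSE)
  if (cfg$context_other_frac < 0 || cfg$context_other_frac >= 1)
    stop("corpus_config: need 0 <= context_other_frac < 1", call. = FALSE)
  structure(cfg, class = "corpus_config")
}

#' @export
print.corpus_config <- function(x, ...) {
  cat("Synthetic corpus configuration\n")
  cat("  essays:", x$n_essays, " (low-effort fraction ",
      x$low_effort_frac, ")\n", sep = "")
  cat("  true mixture: K =", length(x$mu), "\n")
  print(mixture_spec(x$mu, x$sigma, x$pi_base))
  cat("  score link:", x$score_link, " target corr:", x$target_corr, "\n")
  invisible(x)
}

# per-essay mixing proportions for a given ability: logit shift on pi_1,
# remaining mass rescaled pro rata
ability_pi <- function(cfg, ability, noise = 0) {
  p1 <- stats::plogis(stats::qlogis(cfg$pi_base[1L]) -
                        cfg$score_link * ability + noise)
  rest <- cfg$pi_base[-1L]
  c(p1, rest / sum(rest) * (1 - p1))
}

# discretize a noisy ability reading onto the integer score scale
ability_score <- function(ability, noise_sd, scale) {
  z <- (ability + stats::rnorm(length(ability), 0, noise_sd)) /
    sqrt(1 + noise_sd^2)
  lo <- min(scale); hi <- max(scale)
  mid <- (lo + hi) / 2
  as.integer(pmin(pmax(round(mid + (hi - lo) / 4 * z), lo), hi))
}

# negative-binomial event count truncated to [min_events, max_events]
truncated_event_count <- function(events_dist, min_events, max_events) {
  repeat {
    n <- stats::rnbinom(1L, mu = events_dist$mu, size = events_dist$size)
    if (n >= min_events && n <= max_events) return(n)
  }
}

#' Generate one synthetic essay
#'
#' Draws the essay's event count, mixing proportions (via the ability
#' link), pause latencies, character count and strand scores, and returns
#' the essay record together with its truth-ledger entry.
#'
#' Low-effort essays get fewer than 30 events (latencies from the base
#' mixture), both strand scores 0, and a disproportionately large
#' characters-per-pause ratio, mimicking submit-and-quit behaviour.
#'
#' @param config a [corpus_config()].
#' @param ability latent ability on the standard-normal scale (must lie
#'   in `[-6, 6]`).
#' @param seed integer seed for this essay.
#' @param essay_id identifier string.
#' @param low_effort logical; generate a low-effort essay?
#' @return list with `essay` (fields `essay_id`, `pauses`,
#'   `n_chars_typed`, `strand1`, `strand3`, `low_effort`) and `truth`
#'   (one-row data frame).
#' @export
generate_essay <- function(config, ability, seed = NULL,
                           essay_id = "essay", low_effort = FALSE) {
  stopifnot(inherits(config, "corpus_config"))
  if (!is.finite(ability) || abs(ability) > 6)
    stop("ability outside the supported range [-6, 6]", call. = FALSE)
  with_seed(seed, {
    K <- length(config$mu)
    noise_sd <- config$pi_noise_sd *
      (1 + config$pi_noise_het * (1 - stats::pnorm(ability)))
    noise <- stats::rnorm(1L, 0, noise_sd)
    pi_true <- ability_pi(config, ability, noise)

    if (low_effort) {
      n_events <- if (stats::runif(1) < 0.4) sample(0:4, 1L)
                  else sample(5:29, 1L)
      strand1 <- strand3 <- 0L
      # a few words typed, then submitted: large chars-per-pause ratio
      n_chars <- n_events + 4L + stats::rpois(1L, 25)
    } else {
      n_events <- truncated_event_count(config$events_dist,
                                        config$min_events,
                                        config$max_events)
      strand1 <- ability_score(ability, config$score_noise_sd,
                               config$score_scale)
      strand3 <- ability_score(ability, config$score_noise_sd,
                               config$score_scale)
      n_chars <- stats::rpois(1L, 1.69 * n_events)
    }

    n_other <- if (low_effort) 0L else
      round(config$context_other_frac * n_events)
    n_mix <- n_events - n_other
    spec <- mixture_spec(config$mu, config$sigma, pi_true)
    lat_mix <- if (n_mix > 0) sample_mixture_pauses(spec, n_mix) else
      numeric(0)
    ctx <- rep(config$context, n_mix)
    if (n_other > 0L) {
      other <- setdiff(PAUSE_CONTEXTS, config$context)
      ctx_o <- sample(other, n_other, replace = TRUE)
      lat_o <- exp(stats::rnorm(n_other, 5.5, 0.8))
      ord <- sample.int(n_events)
      ctx <- c(ctx, ctx_o)[ord]
      lat <- c(lat_mix, lat_o)[ord]
    } else lat <- lat_mix

    essay <- list(essay_id = essay_id,
                  pauses = data.frame(context = ctx, latency_ms = lat,
                                      stringsAsFactors = FALSE),
                  n_chars_typed = n_chars,
                  strand1 = strand1, strand3 = strand3,
                  low_effort = low_effort)
    truth <- data.frame(essay_id = essay_id, ability = ability,
                        low_effort = low_effort, n_events = n_events,
                        n_analyzed = n_mix,
                        strand1 = strand1, strand3 = strand3,
                        stringsAsFactors = FALSE)
    truth[paste0("pi", seq_len(K))] <- as.list(pi_true)
    truth[paste0("mu", seq_len(K))] <- as.list(config$mu)
    truth[paste0("sigma", seq_len(K))] <- as.list(config$sigma)
    list(essay = essay, truth = truth)
  })
}

#' Generate a synthetic corpus with its truth ledger
#'
#' Produces `n_essays` essay records; `floor(low_effort_frac * n_essays)`
#' of them are low-effort (fewer than 30 events, both scores 0), placed at
#' seeded random positions. All randomness derives from `config$seed`
#' through one child seed per essay, so corpora are reproducible
#' element-wise.
#'
#' @param config a [corpus_config()].
#' @return an object of class `"pause_corpus"`: list with `essays` (list
#'   of essay records), `truth` (data frame aligned by `essay_id`) and
#'   `config`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "corpus_config"))
  n <- config$n_essays
  if (n == 0L)
    return(structure(list(essays = list(),
                          truth = data.frame(essay_id = character(0)),
                          config = config),
                     class = "pause_corpus"))
  n_low <- floor(config$low_effort_frac * n)
  seeds <- split_seed(config$seed, n + 2L)
  low_idx <- with_seed(seeds[n + 1L],
                       sample.int(n, n_low, replace = FALSE))
  abilities <- with_seed(seeds[n + 2L], stats::rnorm(n))
  ids <- sprintf("essay%04d", seq_len(n))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- generate_essay(config, ability = abilities[i],
                               seed = seeds[i], essay_id = ids[i],
                               low_effort = i %in% low_idx)
  }
  truth <- do.call(rbind, lapply(out, `[[`, "truth"))
  structure(list(essays = lapply(out, `[[`, "essay"), truth = truth,
                 config = config),
            class = "pause_corpus")
}

#' @export
print.pause_corpus <- function(x, ...) {
  n <- length(x$essays)
  cat("Synthetic pause corpus:", n, "essays\n")
  if (n) {
    ev <- vapply(x$essays, function(e) nrow(e$pauses), integer(1))
    cat("  pause events per essay: median", stats::median(ev),
        " range", min(ev), "-", max(ev), "\n")
    cat("  low-effort essays:",
        sum(vapply(x$essays, `[[`, logical(1), "low_effort")), "\n")
  }
  invisible(x)
}

#' Calibrate the ability -> pi_1 link slope
#'
#' Finds the `score_link` slope for which the correlation between the true
#' low-component proportion `pi_1` and a strand score matches
#' `target_corr`. Uses a truth-only simulation (no pause latencies are
#' drawn) with common random numbers, and solves for the slope by
#' bisection on a monotone grid.
#'
#' @param config a [corpus_config()]; its `score_link` is ignored.
#' @param target_corr desired Pearson correlation (negative).
#' @param n_sim number of simulated essays used per evaluation.
#' @param seed integer seed for the common random numbers.
#' @return the calibrated slope (numeric scalar).
#' @export
calibrate_score_link <- function(config, target_corr = config$target_corr,
                                 n_sim = 50000L, seed = 1L) {
  stopifnot(inherits(config, "corpus_config"))
  if (target_corr >= 0)
    stop("calibration expects a negative target correlation", call. = FALSE)
  draws <- with_seed(seed, list(
    a = stats::rnorm(n_sim),
    u = stats::rnorm(n_sim),          # pi noise (unit scale)
    v = stats::rnorm(n_sim)))         # score noise (unit scale)
  corr_at <- function(link) {
    noise_sd <- config$pi_noise_sd *
      (1 + config$pi_noise_het * (1 - stats::pnorm(draws$a)))
    p1 <- stats::plogis(stats::qlogis(config$pi_base[1L]) -
                          link * draws$a + noise_sd * draws$u)
    z <- (draws$a + config$score_noise_sd * draws$v) /
      sqrt(1 + config$score_noise_sd^2)
    lo <- min(config$score_scale); hi <- max(config$score_scale)
    s <- pmin(pmax(round((lo + hi) / 2 + (hi - lo) / 4 * z), lo), hi)
    stats::cor(p1, s)
  }
  f <- function(link) corr_at(link) - target_corr
  if (f(0) < 0) stop("target correlation unreachable: noise-free ",
                     "correlation already below target", call. = FALSE)
  upper <- 1
  while (f(upper) > 0 && upper < 64) upper <- upper * 2
  if (f(upper) > 0)
    stop("target correlation unreachable at any slope", call. = FALSE)
  stats::uniroot(f, c(0, upper), tol = 1e-4)$root
}
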