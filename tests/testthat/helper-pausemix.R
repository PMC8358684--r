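# shared fixtures, built in code

# the default well-separated 3-component truth used across tests
default_spec <- function() {
  mixture_spec(mu = c(4.6, 5.8, 7.0), sigma = rep(0.45, 3),
               pi = c(0.55, 0.30, 0.15))
}

# small, fast corpus configuration (event counts scaled down)
quick_config <- function(n_essays = 40, seed = 1L, ...) {
  corpus_config(n_essays = n_essays,
                events_dist = list(mu = 80, size = 2.2),
                seed = seed, ...)
}

# hand-built fit object for exercising selection logic with chosen logliks
fake_fit <- function(K, loglik, converged = TRUE, n_obs = 500L,
                     mu = NULL) {
  if (is.null(mu)) mu <- seq(4, by = 1.2, length.out = K)
  structure(list(
    spec = mixture_spec(mu, rep(0.4, K), rep(1 / K, K)),
    K = as.integer(K), loglik = loglik, converged = converged,
    estimable = TRUE, n_iter = 5L, loglik_trace = loglik,
    n_obs = n_obs, seed = NULL, call = NULL), class = "lnmix")
}

# essay record built directly (for cleaning-rule boundary cases)
make_essay <- function(id, n_events, strand1, strand3, n_chars = 100L,
                       latency = 150) {
  list(essay_id = id,
       pauses = data.frame(
         context = rep("WithinWord", n_events),
         latency_ms = rep(latency, n_events),
         stringsAsFactors = FALSE),
       n_chars_typed = n_chars, strand1 = strand1, strand3 = strand3,
       low_effort = FALSE)
}
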