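test_that("corpus_config validates the generative invariants", {
  expect_s3_class(quick_config(), "corpus_config")
  expect_error(corpus_config(pi_base = c(.6, .3, .2)), "simplex")
  expect_error(corpus_config(sigma = c(.4, 0, .4)), "positive")
  expect_error(corpus_config(mu = c(5, 4.5, 6)), "increasing")
  expect_error(corpus_config(low_effort_frac = 1), "low_effort_frac")
  expect_error(corpus_config(score_link = -1), "nonnegative")
})

test_that("ability link shifts pi_1 monotonically and stays on simplex", {
  cfg <- quick_config(score_link = 0.5)
  # no-link limit: without slope or essay noise, pi equals the baseline
  cfg0 <- quick_config(score_link = 0, pi_noise_sd = 0)
  for (a in c(-2, 0, 1.5)) {
    e0 <- generate_essay(cfg0, ability = a, seed = 1)
    expect_equal(unname(unlist(e0$truth[paste0("pi", 1:3)])),
                 cfg0$pi_base, tolerance = 1e-12)
  }
  # monotone: lower ability => larger low-component proportion
  lows <- generate_essay(cfg, ability = -2, seed = 3)$truth$pi1
  highs <- generate_essay(cfg, ability = 2, seed = 3)$truth$pi1
  expect_gte(lows, highs)
  # simplex for extreme slopes
  cfg_big <- quick_config(score_link = 8)
  tr <- generate_essay(cfg_big, ability = -4, seed = 2)$truth
  pis <- unlist(tr[paste0("pi", 1:3)])
  expect_true(all(pis >= 0))
  expect_equal(sum(pis), 1, tolerance = 1e-12)
  expect_error(generate_essay(cfg, ability = 9), "range")
})

test_that("essay generation is reproducible and honestly labeled", {
  cfg <- quick_config()
  e1 <- generate_essay(cfg, ability = 0.4, seed = 77, essay_id = "x")
  e2 <- generate_essay(cfg, ability = 0.4, seed = 77, essay_id = "x")
  expect_identical(e1, e2)
  le <- generate_essay(cfg, ability = 0, seed = 5, low_effort = TRUE)
  expect_lt(nrow(le$essay$pauses), 30)
  expect_equal(le$essay$strand1, 0L)
  expect_equal(le$essay$strand3, 0L)
})

test_that("corpus generation pins counts, ledger alignment, determinism", {
  cfg <- quick_config(n_essays = 50, low_effort_frac = 0.09, seed = 21)
  co <- generate_corpus(cfg)
  expect_length(co$essays, 50L)
  expect_equal(sum(co$truth$low_effort), floor(0.09 * 50))
  expect_equal(vapply(co$essays, `[[`, character(1), "essay_id"),
               co$truth$essay_id)
  # pi rows on the simplex
  pis <- as.matrix(co$truth[paste0("pi", 1:3)])
  expect_equal(rowSums(pis), rep(1, 50), tolerance = 1e-12)
  # every duration strictly positive, log-durations finite
  lat <- unlist(lapply(co$essays, function(e) e$pauses$latency_ms))
  expect_true(all(lat > 0))
  expect_true(all(is.finite(log(lat))))
  # element-wise reproducibility
  co2 <- generate_corpus(cfg)
  expect_identical(co$truth, co2$truth)
  expect_identical(co$essays[[17]], co2$essays[[17]])
  # empty corpus
  co0 <- generate_corpus(quick_config(n_essays = 0))
  expect_length(co0$essays, 0L)
})

test_that("score link calibration hits the target correlation", {
  cfg <- quick_config(n_essays = 900)
  link <- calibrate_score_link(cfg, target_corr = -0.23,
                               n_sim = 50000, seed = 3)
  expect_gt(link, 0)
  # Monte-Carlo check on generated corpora (truth-only quantities)
  cors <- vapply(1:12, function(r) {
    cc <- quick_config(n_essays = 900, score_link = link,
                       seed = 500 + r)
    tr <- generate_corpus(cc)$truth
    tr <- tr[!tr$low_effort, ]
    cor(tr$pi1, tr$strand1)
  }, numeric(1))
  expect_lt(abs(mean(cors) - (-0.23)), 0.08)
  expect_error(calibrate_score_link(cfg, target_corr = 0.2), "negative")
})

test_that("event counts respect truncation and approximate the target spread", {
  cfg <- corpus_config(n_essays = 120, seed = 9)
  co <- generate_corpus(cfg)
  ev <- co$truth$n_events[!co$truth$low_effort]
  expect_true(all(ev >= 31 & ev <= 2500))
  q <- quantile(ev, c(.25, .5, .75))
  # calibration defaults approximate the intended quartiles loosely
  expect_true(q[1] > 150 && q[1] < 480)
  expect_true(q[2] > 330 && q[2] < 720)
  expect_true(q[3] > 580 && q[3] < 1050)
})
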