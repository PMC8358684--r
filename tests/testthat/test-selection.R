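test_that("free-parameter count follows 3K - 1", {
  expect_equal(count_parameters(1), 2L)
  expect_equal(count_parameters(2:5), c(5L, 8L, 11L, 14L))
  # independent enumeration: K means + K SDs + (K - 1) free weights
  for (K in 1:10)
    expect_equal(count_parameters(K), K + K + (K - 1L))
  expect_error(count_parameters(0), "positive")
})

test_that("information criteria compute their defining formulas", {
  expect_equal(aic(0, 0), 0)
  expect_equal(aic(-100, 8), 216)
  expect_gt(aic(-100, 8), aic(-99, 8))   # monotone in loglik
  expect_equal(bic(-100, 5, 1), 200)     # log(1) = 0
  expect_equal(bic(-100, 8, 100), 200 + 8 * log(100))
  expect_equal(bic(0, 3, exp(2)), 6)
  expect_error(bic(-1, 2, 0), ">= 1")
  expect_error(aic(NaN, 2), "finite")
})

test_that("select_model picks the argmin over converged fits", {
  # identical logliks: penalty decides, smallest K wins
  fits <- list(`2` = fake_fit(2, -100), `3` = fake_fit(3, -100),
               `4` = fake_fit(4, -100), `5` = fake_fit(5, -100))
  rec <- select_model(fits, N = 500)
  expect_equal(rec$chosen_K_aic, 2L)
  expect_equal(rec$chosen_K_bic, 2L)
  expect_true(rec$agreement)

  # crafted logliks where AIC and BIC disagree:
  # AIC prefers K=4 iff ll4 - ll3 > 3; BIC prefers K=3 iff
  # ll4 - ll3 < 1.5 * log(N). With N = 1000 take ll4 - ll3 = 5.
  fits2 <- list(`3` = fake_fit(3, -100), `4` = fake_fit(4, -95))
  rec2 <- select_model(fits2, N = 1000)
  expect_equal(rec2$chosen_K_aic, 4L)
  expect_equal(rec2$chosen_K_bic, 3L)
  expect_false(rec2$agreement)

  # only one converged candidate
  fits3 <- list(`2` = fake_fit(2, -120),
                `3` = fake_fit(3, -100, converged = FALSE))
  rec3 <- select_model(fits3, N = 200)
  expect_equal(rec3$chosen_K_aic, 2L)
  expect_equal(rec3$chosen_K_bic, 2L)

  # nothing converged: classed error
  fits4 <- list(`2` = fake_fit(2, -1, converged = FALSE))
  expect_error(select_model(fits4, N = 100),
               class = "pausemix_no_model")
})

test_that("pairwise mean distances enumerate ordered pairs", {
  s3 <- mixture_spec(c(1, 2, 4), c(.1, .1, .1), rep(1 / 3, 3))
  d <- pairwise_mean_distances(s3)
  expect_length(d, 3L)
  expect_equal(unname(d), c(1, 3, 2))
  expect_named(d, c("1-2", "1-3", "2-3"))
  s4 <- mixture_spec(1:4, rep(.1, 4), rep(.25, 4))
  expect_length(pairwise_mean_distances(s4), 6L)
  expect_length(pairwise_mean_distances(mixture_spec(1, .1, 1)), 0L)
})

test_that("separation summary applies inclusive cut-points", {
  f_wide <- fake_fit(3, -1, mu = c(4, 5.5, 7))    # min distance 1.5
  f_mid <- fake_fit(3, -1, mu = c(4, 4.5, 5))     # min distance 0.5
  f_tight <- fake_fit(3, -1, mu = c(4, 4.2, 4.4)) # min distance 0.2

  s <- separation_summary(list(f_wide, f_wide))
  expect_equal(s$pct_well, 100)
  expect_equal(s$pct_reasonable, 100)

  s2 <- separation_summary(list(f_mid, f_mid))
  expect_equal(s2$pct_well, 0)
  expect_equal(s2$pct_reasonable, 100)

  s3 <- separation_summary(list(f_wide, f_tight))
  expect_equal(s3$pct_well, 50)
  expect_equal(s3$pct_reasonable, 50)

  # boundary is inclusive: distance exactly 1 counts as well separated
  f_edge <- fake_fit(2, -1, mu = c(4, 5))
  expect_equal(separation_summary(list(f_edge))$pct_well, 100)

  # pair-level alternative reading
  sp <- separation_summary(list(f_wide, f_tight), unit = "pair")
  expect_equal(sp$n, 6)
  expect_equal(sp$pct_well, 50)

  expect_error(separation_summary(list()), "empty")
  expect_error(separation_summary(list(f_wide), cut_well = 0.2), "cut_well")
})

test_that("convergence census is nested and non-increasing", {
  conv <- rbind(c(TRUE, TRUE, TRUE, TRUE),
                c(TRUE, TRUE, TRUE, FALSE),
                c(TRUE, FALSE, TRUE, TRUE))
  colnames(conv) <- 2:5
  cen <- convergence_census(conv)
  expect_equal(unname(cen), c(3L, 2L, 2L, 1L))
  expect_true(all(diff(cen) <= 0))

  all_ok <- matrix(TRUE, 5, 4, dimnames = list(NULL, 2:5))
  expect_equal(unname(convergence_census(all_ok)), rep(5L, 4))

  one_fail_last <- all_ok; one_fail_last[2, 4] <- FALSE
  expect_equal(unname(convergence_census(one_fail_last)),
               c(5L, 5L, 5L, 4L))

  empty <- matrix(TRUE, 0, 4, dimnames = list(NULL, 2:5))
  expect_equal(unname(convergence_census(empty)), rep(0L, 4))
})

test_that("AIC never chooses fewer components than BIC when log(N) > 2", {
  set.seed(77)
  for (r in 1:20) {
    lls <- -500 + cumsum(c(0, runif(3, 0, 12)))  # non-decreasing in K
    fits <- lapply(2:5, function(K) fake_fit(K, lls[K - 1L]))
    names(fits) <- 2:5
    rec <- select_model(fits, N = 400)
    expect_gte(rec$chosen_K_aic, rec$chosen_K_bic)
  }
})
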