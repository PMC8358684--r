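test_that("log_transform is elementwise natural log with guards", {
  expect_equal(log_transform(1.0), 0.0)
  expect_equal(log_transform(c(exp(1), exp(2))), c(1, 2))
  expect_error(log_transform(c(2, 0, 3)), "indices 2")
  expect_error(log_transform(c(-1, 5)), "indices 1")
})

test_that("e_step computes posterior responsibilities", {
  # all components identical: uniform responsibilities
  s <- mixture_spec(c(1, 1, 1), c(.5, .5, .5), rep(1 / 3, 3))
  es <- e_step(c(0, 1, 2), s)
  expect_equal(es$resp, matrix(1 / 3, 3, 3), tolerance = 1e-12)
  expect_equal(rowSums(es$resp), rep(1, 3), tolerance = 1e-12)

  # separation limit: far-away component gets ~zero responsibility
  s2 <- mixture_spec(c(0, 100), c(1, 1), c(.5, .5))
  expect_equal(e_step(0, s2)$resp[1, 1], 1, tolerance = 1e-12)

  # hand Bayes: phi(0.5) = phi(-0.5), so posteriors equal the priors
  s3 <- mixture_spec(c(0, 1), c(1, 1), c(.3, .7))
  expect_equal(e_step(0.5, s3)$resp[1, ], c(.3, .7), tolerance = 1e-12)

  # returned loglik equals the summed mixture log-density
  x <- c(-1, 0.2, 3)
  expect_equal(e_step(x, s3)$loglik, sum(mixture_logdensity(x, s3)),
               tolerance = 1e-12)
})

test_that("m_step reduces to weighted moments", {
  # one-hot responsibilities: per-group MLE
  x <- c(0, 0, 10, 10)
  resp <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  s <- m_step(x, resp)
  expect_equal(s$mu, c(0, 10))
  expect_equal(s$pi, c(.5, .5))

  # uniform responsibilities: every component gets the global moments
  xu <- c(1, 2, 3, 4, 5)
  su <- m_step(xu, matrix(1 / 3, 5, 3))
  expect_equal(su$mu, rep(mean(xu), 3))
  sd_pop <- sqrt(mean((xu - mean(xu))^2))
  expect_equal(su$sigma, rep(sd_pop, 3), tolerance = 1e-12)
  expect_equal(su$pi, rep(1 / 3, 3), tolerance = 1e-12)

  expect_error(m_step(x, cbind(c(1, 1, 0, 0), c(0, 0, 1, 0.5))),
               "sum to 1")
})

test_that("single-component fit equals the closed-form MLE", {
  y <- sample_mixture_pauses(mixture_spec(5, .4, 1), 200, seed = 3)
  f <- fit_lnmix(y, K = 1, seed = 1)
  x <- log(y)
  expect_equal(f$spec$mu, mean(x), tolerance = 1e-8)
  expect_equal(f$spec$sigma, sqrt(mean((x - mean(x))^2)),
               tolerance = 1e-6)
  expect_equal(f$spec$pi, 1)
  expect_true(f$converged)
})

test_that("EM ascends the likelihood and orders components", {
  y <- sample_mixture_pauses(default_spec(), 600, seed = 11)
  f <- fit_lnmix(y, 3, seed = 2)
  expect_true(all(diff(f$loglik_trace) >= -1e-10))
  expect_true(!is.unsorted(f$spec$mu))
  expect_lte(f$n_iter, 1000L)
  # loglik consistent with the reported spec
  expect_equal(f$loglik, sum(mixture_logdensity(log(y), f$spec)),
               tolerance = 1e-8)
})

test_that("fit is invariant to shuffling the input order", {
  y <- sample_mixture_pauses(default_spec(), 400, seed = 21)
  f1 <- fit_lnmix(y, 3, seed = 5)
  f2 <- fit_lnmix(sample(y), 3, seed = 5)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
})

test_that("order_components sorts by mu with consistent permutation", {
  s <- mixture_spec(c(7, 5, 6), c(.1, .2, .3), c(.2, .3, .5))
  o <- order_components(s)
  expect_equal(o$mu, c(5, 6, 7))
  expect_equal(o$sigma, c(.2, .3, .1))
  expect_equal(o$pi, c(.3, .5, .2))
  # already ordered: identity; ties keep original index order
  expect_equal(order_components(o), o)
  st <- mixture_spec(c(5, 5), c(.1, .9), c(.4, .6))
  expect_equal(order_components(st)$sigma, c(.1, .9))
})

test_that("too few distinct values yields a non-estimable verdict", {
  f <- fit_lnmix(c(100, 100, 100), K = 2)
  expect_false(f$estimable)
  expect_false(f$converged)
  expect_true(is.na(f$loglik))
})

test_that("degeneracy guards keep sigma floored and loglik finite", {
  # many exact repeats invite a collapsing component
  y <- c(rep(100, 50), sample_mixture_pauses(mixture_spec(6, .5, 1),
                                             50, seed = 2))
  f <- fit_lnmix(y, 2, seed = 4)
  expect_true(all(f$spec$sigma >= 1e-3))
  expect_true(is.finite(f$loglik))
})

test_that("parameter recovery improves with sample size", {
  spec <- default_spec()
  bias <- sapply(c(200, 2000, 20000), function(n) {
    errs <- sapply(1:5, function(r) {
      y <- sample_mixture_pauses(spec, n, seed = 42 + n + r)
      f <- fit_lnmix(y, 3, seed = r, n_restarts = 3)
      max(abs(f$spec$mu - spec$mu))
    })
    mean(errs)
  })
  expect_lt(bias[2], bias[1])
  expect_lt(bias[3], bias[2])
  expect_lt(bias[3], 0.06)
})

test_that("EM matches an independent mixture fitter on shared data", {
  library(mclust)
  y <- sample_mixture_pauses(default_spec(), 1000, seed = 31)
  x <- log(y)
  f <- fit_lnmix(y, 3, seed = 1)
  mc <- mclust::Mclust(x, G = 3, modelNames = "V", verbose = FALSE)
  # same solution up to small numerical differences
  expect_equal(sort(f$spec$mu), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.02)
  expect_equal(f$loglik, mc$loglik, tolerance = 1e-3)
})

test_that("lnmix methods are coherent", {
  y <- sample_mixture_pauses(default_spec(), 500, seed = 13)
  f <- fit_lnmix(y, 3, seed = 1)
  cf <- coef(f)
  expect_named(cf, c("mu1", "mu2", "mu3", "sigma1", "sigma2", "sigma3",
                     "pi1", "pi2", "pi3"))
  ll <- logLik(f)
  expect_equal(attr(ll, "df"), 8L)
  expect_equal(AIC(f), aic(f$loglik, 8))
  expect_equal(BIC(f), bic(f$loglik, 8, 500))
  expect_equal(predict(f, c(100, 200)),
               mixture_logdensity(log(c(100, 200)), f$spec))
  r <- predict(f, y[1:10], type = "responsibility")
  expect_equal(rowSums(r), rep(1, 10), tolerance = 1e-10)
  # quantile residuals roughly standard normal
  res <- residuals(f, y)
  expect_lt(abs(mean(res)), 0.15)
  expect_lt(abs(sd(res) - 1), 0.15)
  sim <- simulate(f, seed = 9)
  expect_length(sim, 500)
  expect_output(print(summary(f)), "AIC")
})
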