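# Conjugate-normal testing example: all quantities have closed forms, and
# the module doubles as the oracle for the MCMC Bayes-factor estimators.

test_that("posterior mean and SD combine sample and prior precision", {
  post <- posterior_normal(100, 0.258, 2)
  expect_equal(post$mu1, 100 * 0.258 / 100.25)
  expect_equal(post$sigma1, 1 / sqrt(100.25))
  expect_equal(post$mu1, 0.25736, tolerance = 1e-4)
  expect_equal(post$sigma1, 0.09988, tolerance = 1e-4)
  expect_equal(posterior_normal(50, 0, 1)$mu1, 0)
  # flat-prior limit: mu1 -> xbar, sigma1^2 -> 1/n
  flat <- posterior_normal(100, 0.258, 1e6)
  expect_equal(flat$mu1, 0.258, tolerance = 1e-8)
  expect_equal(flat$sigma1^2, 1 / 100, tolerance = 1e-8)
})

test_that("the LRT uses n*xbar^2 against chi-square(1)", {
  l1 <- lrt_normal(100, 0.258)
  expect_equal(l1$statistic, 6.6564)
  expect_equal(round(l1$p_value, 2), 0.01)
  expect_true(l1$reject)
  l2 <- lrt_normal(100, 0.196)
  expect_equal(l2$statistic, 3.8416)
  expect_equal(round(l2$p_value, 2), 0.05)
  l0 <- lrt_normal(100, 0)
  expect_equal(l0$statistic, 0)
  expect_equal(l0$p_value, 1)
  expect_false(l0$reject)
  expect_equal(l1$critical, stats::qchisq(0.95, 1))
})

test_that("the CI criterion equals |mu1| > z * sigma1 and inflates the LRT
           cutoff by 1 + 1/(n sigma0^2)", {
  set.seed(51)
  for (i in 1:30) {
    n <- sample(10:1e4, 1); xbar <- stats::rnorm(1, 0, 0.3)
    s0 <- stats::runif(1, 0.2, 10)
    ci <- ci_rejects(n, xbar, s0)
    post <- posterior_normal(n, xbar, s0)
    expect_identical(ci$reject,
                     abs(post$mu1) > stats::qnorm(0.975) * post$sigma1)
  }
  thr <- ci_rejects(100, 0.258, 2)$threshold
  expect_equal(thr, stats::qchisq(0.95, 1) * (1 + 1 / 400))
  expect_equal(thr, 3.8496, tolerance = 0.01)
  expect_false(ci_rejects(100, 0, 2)$reject)
})

test_that("the closed-form Bayes factor equals the marginal-likelihood
           ratio of the two normal densities", {
  set.seed(52)
  for (i in 1:30) {
    n <- sample(5:5000, 1); xbar <- stats::rnorm(1, 0, 0.5)
    s0 <- stats::runif(1, 0.1, 5)
    oracle <- stats::dnorm(xbar, 0, sqrt(1 / n + s0^2)) /
      stats::dnorm(xbar, 0, sqrt(1 / n))
    expect_equal(bf_normal(n, xbar, s0), oracle, tolerance = 1e-10)
  }
  expect_equal(bf_normal(100, 0.258, 2), 1.381, tolerance = 1e-3)
  expect_equal(bf_normal(100, 0, 2), 1 / sqrt(401))
  expect_equal(bf_normal(100, 0.258, 1e-8), 1, tolerance = 1e-6)
})

test_that("posterior model probabilities map B10 through B/(1+B)", {
  expect_equal(posterior_model_prob(19), 0.95)
  expect_equal(posterior_model_prob(1), 0.5)
  expect_equal(posterior_model_prob(0.359), 0.264, tolerance = 1e-3)
  expect_equal(posterior_model_prob(Inf), 1)
  expect_equal(posterior_model_prob(1, prior_odds = 3), 0.75)
})

test_that("the threshold form of the BF rule agrees exactly with
           B10 > 19", {
  set.seed(53)
  for (i in 1:200) {
    n <- sample(5:1e5, 1); xbar <- stats::rnorm(1, 0, 0.4)
    s0 <- stats::runif(1, 0.1, 10)
    expect_identical(bf_rejects(n, xbar, s0)$reject,
                     bf_normal(n, xbar, s0) > 19)
  }
  # worked threshold: 2 * 1.0025 * log(19 * sqrt(401)) ~ 11.91
  expect_equal(bf_rejects(100, 0.1, 2)$threshold_stat,
               2 * 1.0025 * log(19 * sqrt(401)))
  expect_equal(bf_rejects(100, 0.1, 2)$threshold_stat, 11.91,
               tolerance = 1e-2)
  expect_false(bf_rejects(100, 0.258, 2)$reject)   # B10 = 1.381 < 19
})

test_that("thresholds are strictly ordered LRT < CI < BF and rejection
           regions are nested", {
  for (n in c(10, 100, 1e4, 1e6)) {
    for (s0 in c(0.5, 1, 2, 10)) {
      th <- test_thresholds(n, s0)
      expect_lt(th[["lrt"]], th[["ci"]])
      expect_lt(th[["ci"]], th[["bf"]])
    }
  }
  set.seed(54)
  for (i in 1:100) {
    n <- sample(10:1e4, 1); xbar <- stats::rnorm(1, 0, 0.5)
    s0 <- stats::runif(1, 0.3, 5)
    bf <- bf_rejects(n, xbar, s0)$reject
    ci <- ci_rejects(n, xbar, s0)$reject
    lrt <- lrt_normal(n, xbar)$reject
    expect_true(!bf || ci)    # BF-reject implies CI-reject
    expect_true(!ci || lrt)   # CI-reject implies LRT-reject
  }
})

test_that("diffuse priors produce the Jeffreys paradox: LRT rejects while
           the Bayes factor favors the null", {
  res <- normal_example(100, 2.58 / sqrt(100), sigma0 = 10)
  expect_true(res$lrt_reject)
  expect_lt(res$b10, 1)
  expect_lt(res$p_h1, 0.5)
  expect_false(res$bf_reject)
})

test_that("the analytic null-region Bayes factor converges to the
           closed form as eps -> 0", {
  b_lim <- bf_normal(100, 0.258, 2)
  b_eps <- null_region_bf_normal(100, 0.258, 2, eps = 1e-6)
  expect_lt(abs(b_eps - b_lim) / b_lim, 1e-4)
  # widening the null region swallows posterior mass, so over a broad
  # range the curve falls monotonically as eps grows and climbs back to
  # the density-ratio limit as eps -> 0
  eps_grid <- 10^seq(-3, log10(0.3), length.out = 25)
  curve <- vapply(eps_grid, function(e)
    null_region_bf_normal(100, 0.258, 2, e), numeric(1))
  expect_true(all(diff(curve) < 0))
  expect_equal(curve[1], b_lim, tolerance = 1e-3)
  expect_lt(curve[length(curve)], 0.1)
})

test_that("B10 shrinks to zero as data accumulate under a true null", {
  set.seed(55)
  med_b <- vapply(c(1e3, 1e5), function(n) {
    xbar <- stats::rnorm(50, 0, 1 / sqrt(n))
    stats::median(vapply(xbar, function(x) bf_normal(n, x, 2),
                         numeric(1)))
  }, numeric(1))
  expect_lt(med_b[2], med_b[1])
  expect_lt(med_b[2], 0.05)
})

test_that("sampled exact posteriors reproduce their moments and feed the
           MCMC null-region estimator", {
  tr <- sample_posterior(100, 0.258, 2, N = 2e5, seed = 56)
  post <- posterior_normal(100, 0.258, 2)
  expect_lt(abs(mean(tr) - post$mu1), 3 * post$sigma1 / sqrt(2e5))
  expect_equal(stats::sd(tr), post$sigma1, tolerance = 0.01)
  prior_cdf <- function(eps) 1 - 2 * stats::pnorm(-eps / 2)
  b_mc <- bf_null_region(tr, prior_cdf, eps = 0.01)$b10
  b_exact <- null_region_bf_normal(100, 0.258, 2, eps = 0.01)
  expect_equal(b_mc, b_exact, tolerance = 0.15)
})

test_that("the full report aggregates all criteria coherently", {
  res <- normal_example(100, 0.258, 2)
  expect_s3_class(res, "normal_example_result")
  expect_equal(res$p_h1, res$b10 / (1 + res$b10))
  expect_true(res$lrt_reject)
  expect_true(res$ci_reject)    # 6.6564 exceeds the CI threshold 3.851
  expect_false(res$bf_reject)   # but B10 = 1.381 is far below 19
  expect_output(print(res), "B10")
})
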