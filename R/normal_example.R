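# Fully analytic conjugate-normal testing example.
#
# Test H0: mu = 0 against H1: mu != 0 from a sample of size n from
# N(mu, 1), summarized by the sample mean xbar, with prior
# mu ~ N(0, sigma0^2) under H1.  Everything has closed form: the posterior
# is N(mu1, sigma1^2) with mu1 = n*xbar/(n + 1/sigma0^2) and
# 1/sigma1^2 = n + 1/sigma0^2; the LRT statistic is n*xbar^2 ~ chi^2_1
# under H0; and the Bayes factor is
#   B10 = (1 + n sigma0^2)^(-1/2) exp{ n xbar^2 / (2 [1 + 1/(n sigma0^2)]) },
# identical to the Savage-Dickey ratio pi(0)/pi(0|x) for this model.  The
# example doubles as the validation oracle for the MCMC-based Bayes-factor
# estimators: the exact posterior can be sampled and fed to them.
#
# Note on parameterization: data enter only through the standardized mean
# z = sqrt(n)*|xbar| (so the LRT statistic n*xbar^2 equals z^2 and the 5%
# cutoff is 3.84); tabled values quoted as "n|xbar|" are this z.

.check_normal_input <- function(n, xbar, sigma0, alpha = 0.05) {
  stopifnot(n >= 1, sigma0 > 0, alpha > 0, alpha < 1)
  invisible(NULL)
}

#' Conjugate-normal posterior
#'
#' @param n sample size; `xbar` sample mean; `sigma0` prior SD of mu.
#' @return list with posterior mean `mu1` and SD `sigma1`.
#' @export
posterior_normal <- function(n, xbar, sigma0) {
  .check_normal_input(n, xbar, sigma0)
  prec <- n + 1 / sigma0^2
  list(mu1 = n * xbar / prec, sigma1 = 1 / sqrt(prec))
}

#' Likelihood-ratio test for the normal example
#'
#' Statistic 2*dlogL = n*xbar^2, chi^2_1 under H0.
#'
#' @inheritParams posterior_normal
#' @param alpha significance level.
#' @return list with `statistic`, `p_value`, `reject`, `critical`.
#' @export
lrt_normal <- function(n, xbar, alpha = 0.05) {
  stopifnot(n >= 1, alpha > 0, alpha < 1)
  stat <- n * xbar^2
  crit <- stats::qchisq(1 - alpha, df = 1)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       reject = stat > crit, critical = crit)
}

#' Posterior credibility-interval test
#'
#' Rejects H0 when the (1 - alpha) posterior CI mu1 +/- z * sigma1 excludes
#' 0, equivalently when n*xbar^2 exceeds the LRT cutoff inflated by
#' \[1 + 1/(n sigma0^2)\].
#'
#' @inheritParams posterior_normal
#' @param alpha CI significance level.
#' @return list with `reject`, `threshold` (on the n*xbar^2 scale) and the
#'   CI endpoints.
#' @export
ci_rejects <- function(n, xbar, sigma0, alpha = 0.05) {
  .check_normal_input(n, xbar, sigma0, alpha)
  post <- posterior_normal(n, xbar, sigma0)
  zq <- stats::qnorm(1 - alpha / 2)
  thr <- zq^2 * (1 + 1 / (n * sigma0^2))
  list(reject = n * xbar^2 > thr, threshold = thr,
       ci = post$mu1 + c(-1, 1) * zq * post$sigma1)
}

#' Closed-form Bayes factor for the normal example
#'
#' \deqn{B_{10} = \frac{\phi(\bar x; 0, 1/n + \sigma_0^2)}
#'                     {\phi(\bar x; 0, 1/n)}
#'             = (1 + n\sigma_0^2)^{-1/2}
#'               \exp\!\left\{\frac{n\bar x^2}
#'                                 {2[1 + 1/(n\sigma_0^2)]}\right\}.}
#'
#' @inheritParams posterior_normal
#' @return the Bayes factor B10 in favor of H1.
#' @export
bf_normal <- function(n, xbar, sigma0) {
  .check_normal_input(n, xbar, sigma0)
  exp(n * xbar^2 / (2 * (1 + 1 / (n * sigma0^2)))) / sqrt(1 + n * sigma0^2)
}

#' Posterior model probability from a Bayes factor
#'
#' P(H1 | x) = pi1 B10 / (pi0 + pi1 B10); with equal prior model
#' probabilities this is B10 / (1 + B10), so a 95% cutoff on P(H1|x)
#' corresponds to B10 = 19.
#'
#' @param b10 Bayes factor (>= 0, may be Inf).
#' @param prior_odds prior odds pi1/pi0 (default 1).
#' @export
posterior_model_prob <- function(b10, prior_odds = 1) {
  stopifnot(b10 >= 0, prior_odds > 0)
  if (is.infinite(b10)) return(1)
  b10 * prior_odds / (1 + b10 * prior_odds)
}

#' Bayes-factor rejection rule
#'
#' Rejects H0 when B10 exceeds `threshold` (default 19, the 95% posterior
#' cutoff), equivalently when
#' \deqn{n\bar x^2 > 2[1 + 1/(n\sigma_0^2)]
#'       \log\{ \mathrm{thr}\sqrt{1 + n\sigma_0^2} \}.}
#' The two forms agree exactly (algebraic identity, cross-checked in tests).
#'
#' @inheritParams posterior_normal
#' @param threshold Bayes-factor cutoff.
#' @return list with `reject` and `threshold_stat` (on the n*xbar^2 scale).
#' @export
bf_rejects <- function(n, xbar, sigma0, threshold = 19) {
  .check_normal_input(n, xbar, sigma0)
  thr <- 2 * (1 + 1 / (n * sigma0^2)) *
    log(threshold * sqrt(1 + n * sigma0^2))
  list(reject = n * xbar^2 > thr, threshold_stat = thr)
}

#' Rejection thresholds of the three criteria
#'
#' On the n*xbar^2 scale, the LRT, posterior-CI and Bayes-factor thresholds
#' are ordered
#' \deqn{\chi^2_{1,\alpha} < \chi^2_{1,\alpha}[1 + 1/(n\sigma_0^2)]
#'       < 2[1 + 1/(n\sigma_0^2)]\log\{19\sqrt{1+n\sigma_0^2}\},}
#' so the rejection regions are nested (BF subset of CI subset of LRT): the
#' LRT has the most power and the highest false-positive rate, the
#' Bayes-factor test is the most conservative.  The last inequality holds
#' whenever log(thr * sqrt(1 + n sigma0^2)) > chi^2_quantile/2, which is
#' automatic at the defaults (thr = 19 > e^1.92).
#'
#' @inheritParams posterior_normal
#' @param alpha significance level; `threshold` Bayes-factor cutoff.
#' @return named numeric `c(lrt=, ci=, bf=)`.
#' @export
test_thresholds <- function(n, sigma0, alpha = 0.05, threshold = 19) {
  stopifnot(n >= 1, sigma0 > 0)
  q <- stats::qchisq(1 - alpha, df = 1)
  infl <- 1 + 1 / (n * sigma0^2)
  c(lrt = q, ci = q * infl,
    bf = 2 * infl * log(threshold * sqrt(1 + n * sigma0^2)))
}

#' Analytic null-region Bayes factor for the normal example
#'
#' Closed-form evaluation of the null-region odds ratio with
#' P(R) = P(|mu| < eps) = 1 - 2 Phi(-eps/sigma0) under the prior and
#' P(R|x) = Phi((eps - mu1)/sigma1) - Phi((-eps - mu1)/sigma1) under the
#' posterior.  Converges to [bf_normal()] as eps -> 0.
#'
#' @inheritParams posterior_normal
#' @param eps null-region half-width (> 0).
#' @return the Bayes factor B10,eps.
#' @export
null_region_bf_normal <- function(n, xbar, sigma0, eps) {
  .check_normal_input(n, xbar, sigma0)
  stopifnot(eps > 0)
  post <- posterior_normal(n, xbar, sigma0)
  p_prior <- 1 - 2 * stats::pnorm(-eps / sigma0)
  p_post <- stats::pnorm((eps - post$mu1) / post$sigma1) -
    stats::pnorm((-eps - post$mu1) / post$sigma1)
  if (p_prior >= 1 - 1e-12 && p_post >= 1 - 1e-12) return(1)
  if (p_post >= 1) return(0)
  ((1 - p_post) / p_post) / ((1 - p_prior) / p_prior)
}

#' Sample the exact conjugate posterior
#'
#' Validation bridge to the MCMC-based Bayes-factor estimators: N draws from
#' N(mu1, sigma1^2).
#'
#' @inheritParams posterior_normal
#' @param N number of draws; `seed` optional seed.
#' @return an [mcmc_trace()] of mu samples.
#' @export
sample_posterior <- function(n, xbar, sigma0, N, seed = NULL) {
  .check_normal_input(n, xbar, sigma0)
  stopifnot(N >= 1)
  if (!is.null(seed)) set.seed(seed)
  post <- posterior_normal(n, xbar, sigma0)
  mcmc_trace(stats::rnorm(N, post$mu1, post$sigma1), parameter = "mu")
}

#' Full report for the conjugate-normal example
#'
#' Runs all criteria on one dataset and returns a table-style row: posterior
#' summaries, LRT statistic and p-value, CI decision, Bayes factor,
#' posterior model probability, BF decision, and the ordered thresholds.
#'
#' @inheritParams posterior_normal
#' @param alpha significance level; `bf_threshold` Bayes-factor cutoff.
#' @return an object of class `normal_example_result`.
#' @export
normal_example <- function(n, xbar, sigma0, alpha = 0.05,
                           bf_threshold = 19) {
  .check_normal_input(n, xbar, sigma0, alpha)
  post <- posterior_normal(n, xbar, sigma0)
  lrt <- lrt_normal(n, xbar, alpha)
  ci <- ci_rejects(n, xbar, sigma0, alpha)
  b10 <- bf_normal(n, xbar, sigma0)
  bf <- bf_rejects(n, xbar, sigma0, bf_threshold)
  structure(list(n = n, xbar = xbar, sigma0 = sigma0, alpha = alpha,
                 bf_threshold = bf_threshold,
                 mu1 = post$mu1, sigma1 = post$sigma1,
                 lrt_stat = lrt$statistic, p_value = lrt$p_value,
                 lrt_reject = lrt$reject,
                 ci = ci$ci, ci_reject = ci$reject,
                 b10 = b10, p_h1 = posterior_model_prob(b10),
                 bf_reject = bf$reject,
                 thresholds = test_thresholds(n, sigma0, alpha,
                                              bf_threshold)),
            class = "normal_example_result")
}

#' @export
print.normal_example_result <- function(x, ...) {
  cat(sprintf("Normal example: n = %d, xbar = %g (sqrt(n)|xbar| = %.3f), ",
              x$n, x$xbar, sqrt(x$n) * abs(x$xbar)))
  cat(sprintf("prior mu ~ N(0, %g^2)\n", x$sigma0))
  cat(sprintf("  posterior mu | x ~ N(%.5f, %.5f^2)\n", x$mu1, x$sigma1))
  cat(sprintf("  LRT: 2*dlogL = %.4f, p = %.4g  -> %s H0\n",
              x$lrt_stat, x$p_value,
              if (x$lrt_reject) "reject" else "retain"))
  cat(sprintf("  95%% posterior CI: (%.5f, %.5f)  -> %s H0\n",
              x$ci[1], x$ci[2], if (x$ci_reject) "reject" else "retain"))
  cat(sprintf("  B10 = %.4g, P(H1|x) = %.4g  -> %s H0 (cutoff B10 > %g)\n",
              x$b10, x$p_h1, if (x$bf_reject) "reject" else "retain",
              x$bf_threshold))
  th <- x$thresholds
  cat(sprintf("  thresholds on n*xbar^2: LRT %.4f < CI %.4f < BF %.4f\n",
              th["lrt"], th["ci"], th["bf"]))
  invisible(x)
}
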