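# Savage-Dickey density-ratio Bayes factors from MCMC posterior samples.
#
# For nested models H0: phi = phi0 vs H1: phi free (priors on shared
# parameters agreeing at the null), the Bayes factor equals the prior to
# posterior density ratio at the null value,
#   B10 = pi(phi0) / pi(phi0 | x),
# estimable from within-model MCMC output alone.  Two estimators are
# provided: a Gaussian kernel density estimate of the posterior ordinate
# (with boundary reflection), and the null-region odds ratio
#   B10,eps = [(1 - P(R|x)) / P(R|x)] / [(1 - P(R)) / P(R)],
# with R the region within eps of the null, which converges to the density
# ratio as eps -> 0 and avoids density estimation at a boundary.

#' Read a parameter trace from an MCMC sample file
#'
#' The expected dialect is a whitespace/tab-delimited file with a header row
#' of parameter names and one posterior sample per row (the `mcmc.txt`
#' format of coalescent MCMC programs).
#'
#' @param path file path.
#' @param column name of the column to extract.
#' @param burnin fraction of initial samples to discard (in \[0, 1)).
#' @return an object of class `mcmc_trace`: a numeric vector with attributes
#'   `parameter`, `source`, `n_burnin`.
#' @export
read_trace <- function(path, column, burnin = 0) {
  stopifnot(burnin >= 0, burnin < 1)
  df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!column %in% names(df))
    stop("column '", column, "' not found; available: ",
         paste(names(df), collapse = ", "))
  x <- df[[column]]
  if (!is.numeric(x)) {
    xn <- suppressWarnings(as.numeric(x))
    if (anyNA(xn))
      stop("non-numeric value in column '", column, "' at row ",
           which(is.na(xn))[1])
    x <- xn
  }
  nb <- floor(burnin * length(x))
  if (nb > 0) x <- x[-seq_len(nb)]
  mcmc_trace(x, parameter = column, source = path, n_burnin = nb)
}

#' Construct an MCMC trace object
#'
#' @param x numeric vector of posterior samples (finite, length >= 1).
#' @param parameter,source,n_burnin provenance attributes.
#' @export
mcmc_trace <- function(x, parameter = "phi", source = NA_character_,
                       n_burnin = 0L) {
  x <- as.numeric(x)
  if (!length(x)) stop("empty trace")
  if (!all(is.finite(x))) stop("trace contains non-finite values")
  structure(x, parameter = parameter, source = source,
            n_burnin = n_burnin, class = "mcmc_trace")
}

#' @export
print.mcmc_trace <- function(x, ...) {
  cat(sprintf("mcmc_trace '%s': N = %d, mean = %.5g, sd = %.5g\n",
              attr(x, "parameter"), length(x), mean(x), stats::sd(x)))
  invisible(x)
}

#' Kernel bandwidth for posterior density smoothing
#'
#' The rule of Silverman (1986, eq. 3.30-3.31):
#' \deqn{h = 0.9 \min(\mathrm{SD}, \mathrm{IQR}/1.34)\, N^{-1/5}.}
#'
#' @param trace numeric vector of posterior samples (N >= 2).
#' @return the bandwidth h.
#' @export
sd_bandwidth <- function(trace) {
  x <- as.numeric(trace)
  if (length(x) < 2) stop("bandwidth needs N >= 2 samples")
  spread <- min(stats::sd(x), stats::IQR(x) / 1.34)
  if (!is.finite(spread) || spread <= 0)
    stop("degenerate trace: zero spread")
  0.9 * spread * length(x)^(-1 / 5)
}

#' Gaussian kernel density estimate at a point
#'
#' \deqn{\hat\pi(x_0\mid x) = \frac{1}{Nh}\sum_i K\!\left(\frac{x_0 -
#'   x^{(i)}}{h}\right)}, with the standard normal kernel
#' K(t) = exp(-t^2/2)/sqrt(2 pi).  If a boundary interval is supplied,
#' samples are mirrored across each finite endpoint (reflection correction),
#' appropriate when the evaluation point sits at or near a support boundary.
#'
#' @param trace numeric vector of posterior samples.
#' @param x0 evaluation point.
#' @param h bandwidth (> 0); default [sd_bandwidth()].
#' @param boundary optional support interval `c(lo, hi)` (entries may be
#'   infinite); finite endpoints get reflection.
#' @return the density estimate at `x0`.
#' @export
kde_at <- function(trace, x0, h = NULL, boundary = NULL) {
  x <- as.numeric(trace)
  if (is.null(h)) h <- sd_bandwidth(x)
  stopifnot(h > 0)
  d <- sum(stats::dnorm((x0 - x) / h))
  if (!is.null(boundary)) {
    if (is.finite(boundary[1]))
      d <- d + sum(stats::dnorm((x0 - (2 * boundary[1] - x)) / h))
    if (length(boundary) > 1 && is.finite(boundary[2]))
      d <- d + sum(stats::dnorm((x0 - (2 * boundary[2] - x)) / h))
  }
  d / (length(x) * h)
}

#' Beta prior specification
#'
#' @param a,b positive shape parameters of a beta(a, b) prior on an
#'   introgression probability.
#' @export
beta_prior <- function(a, b) {
  stopifnot(a > 0, b > 0)
  structure(list(a = a, b = b), class = "beta_prior")
}

.bf_result <- function(b10, method, eps = NA_real_, prior_prob = NA_real_,
                       post_prob = NA_real_, n = NA_integer_,
                       lower_bound = NA_real_) {
  structure(list(b10 = b10, method = method, eps = eps,
                 prior_prob = prior_prob, post_prob = post_prob,
                 n = n, evidence = classify_evidence(b10),
                 lower_bound = lower_bound),
            class = "bayes_factor_result")
}

#' @export
print.bayes_factor_result <- function(x, ...) {
  b <- if (is.infinite(x$b10))
    sprintf("Inf (lower bound %.4g)", x$lower_bound)
  else sprintf("%.4g", x$b10)
  cat(sprintf("B10 = %s [%s, %s evidence for introgression]\n",
              b, x$method, x$evidence))
  if (!is.na(x$eps))
    cat(sprintf("  eps = %g, P(null region) prior %.4g -> posterior %.4g",
                x$eps, x$prior_prob, x$post_prob), "\n")
  invisible(x)
}

#' Savage-Dickey Bayes factor by kernel density estimation
#'
#' B10 = pi(phi0) / pi-hat(phi0 | x), the prior ordinate at the null divided
#' by the kernel density estimate of the posterior ordinate, with boundary
#' reflection by default (the null value of an introgression probability
#' sits at the boundary of \[0, 1\]).
#'
#' @param trace posterior samples ([mcmc_trace()] or numeric).
#' @param prior prior density at the null value: a positive number, a
#'   [beta_prior()], or a density function evaluated at `null_value`.
#' @param null_value the null parameter value (default 0).
#' @param h bandwidth; default [sd_bandwidth()].
#' @param boundary support interval for reflection (default `c(0, 1)`).
#' @return a `bayes_factor_result`; an underflowing posterior ordinate gives
#'   B10 = Inf with a finite lower bound (computed as if a single sample sat
#'   at the null).
#' @export
bf_savage_dickey_kde <- function(trace, prior, null_value = 0, h = NULL,
                                 boundary = c(0, 1)) {
  x <- as.numeric(trace)
  if (is.null(h)) h <- sd_bandwidth(x)
  p0 <- if (inherits(prior, "beta_prior"))
    stats::dbeta(null_value, prior$a, prior$b)
  else if (is.function(prior)) prior(null_value)
  else as.numeric(prior)
  if (!is.finite(p0) || p0 <= 0)
    stop("prior density at the null value must be finite and positive")
  post <- kde_at(x, null_value, h = h, boundary = boundary)
  if (post > 0) {
    .bf_result(p0 / post, "kde", n = length(x))
  } else {
    refl <- 1 + sum(is.finite(boundary))
    post_min <- refl * stats::dnorm(0) / (length(x) * h)
    .bf_result(Inf, "kde", n = length(x), lower_bound = p0 / post_min)
  }
}

#' Savage-Dickey Bayes factor by the null-region odds ratio
#'
#' With null region R: |phi - phi0| < eps (for a probability parameter with
#' phi0 = 0: phi < eps), B10 is the ratio of posterior to prior odds against
#' the null region; the prior probability P(R) comes from the prior CDF and
#' the posterior probability P(R|x) is the fraction of MCMC samples inside
#' the region.  When no sample falls inside, B10 = Inf is reported together
#' with a finite lower bound obtained by substituting
#' P(R|x) = 1/(N+1) (the zero-successes-in-N rule).
#'
#' @param trace posterior samples.
#' @param prior a [beta_prior()] (null region \[0, eps)) or a function
#'   returning the prior probability of the null region given eps.
#' @param eps half-width of the null region (default 0.01; results should be
#'   insensitive to eps, e.g. 0.001 gives very similar values for smooth
#'   posteriors).
#' @param null_value null value (default 0; samples within eps of it count).
#' @return a `bayes_factor_result`.
#' @export
bf_null_region <- function(trace, prior, eps = 0.01, null_value = 0) {
  stopifnot(eps > 0)
  x <- as.numeric(trace)
  N <- length(x)
  p_prior <- if (inherits(prior, "beta_prior")) {
    if (eps >= 1) stop("eps outside the support of a beta prior")
    stats::pbeta(eps, prior$a, prior$b)
  } else if (is.function(prior)) prior(eps)
  else stop("'prior' must be a beta_prior or a prior-CDF function")
  if (!is.finite(p_prior) || p_prior <= 0 || p_prior >= 1)
    stop("prior probability of the null region must lie in (0, 1)")
  p_post <- mean(abs(x - null_value) < eps)
  prior_odds <- (1 - p_prior) / p_prior
  if (p_post == 0) {
    lb <- ((1 - 1 / (N + 1)) / (1 / (N + 1))) / prior_odds
    .bf_result(Inf, "null-region", eps = eps, prior_prob = p_prior,
               post_prob = 0, n = N, lower_bound = lb)
  } else {
    b10 <- ((1 - p_post) / p_post) / prior_odds
    .bf_result(b10, "null-region", eps = eps, prior_prob = p_prior,
               post_prob = p_post, n = N)
  }
}

#' Evidence label for a Bayes factor
#'
#' B10 >= 20 is strong evidence for introgression (95% posterior model
#' probability at equal prior odds); B10 >= 100 is extremely strong (99%).
#'
#' @param b10 Bayes factor (>= 0, may be Inf).
#' @return one of `"none/weak"`, `"strong"`, `"extremely strong"`.
#' @export
classify_evidence <- function(b10) {
  stopifnot(b10 >= 0)
  if (b10 >= 100) "extremely strong"
  else if (b10 >= 20) "strong"
  else "none/weak"
}
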