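# HYDE estimator/test and the ABBA-BABA D-statistic.

#' Site-pattern probabilities under the hybridization mixture
#'
#' Under the symmetric hybrid-speciation model, gene trees (and hence site
#' patterns) are a mixture over the two parental species trees S1 and S2 with
#' weights phi and 1 - phi.  With matching-class probability `a` and
#' mismatching-class probability `b` (b < a) under either parental tree, the
#' informative pattern probabilities are
#' \deqn{p_{iijj} = \phi a + (1-\phi) b, \quad p_{ijij} = b, \quad
#'       p_{ijji} = \phi b + (1-\phi) a.}
#'
#' @param phi mixture weight (introgression probability) in \[0, 1\].
#' @param a,b matching and mismatching class probabilities, with
#'   0 <= b < a and a + 2b <= 1.
#' @return named numeric vector `c(iijj=, ijij=, ijji=)`.
#' @export
pattern_probs_mixture <- function(phi, a, b) {
  stopifnot(phi >= 0, phi <= 1, b >= 0, b < a, a + 2 * b <= 1)
  c(iijj = phi * a + (1 - phi) * b,
    ijij = b,
    ijji = phi * b + (1 - phi) * a)
}

# pull the three informative weights (and the grand total) out of whatever
# count representation the caller supplies
.informative_counts <- function(counts) {
  if (inherits(counts, "site_pattern_counts")) {
    n3 <- counts$totals[INFORMATIVE_CLASSES]
    ntot <- sum(counts$totals) - counts$totals[["skipped"]]
  } else if (is.numeric(counts)) {
    if (!is.null(names(counts)) && all(INFORMATIVE_CLASSES %in%
                                       names(counts))) {
      n3 <- counts[INFORMATIVE_CLASSES]
      ntot <- sum(counts[setdiff(names(counts), "skipped")])
    } else if (length(counts) == 3L) {
      n3 <- stats::setNames(counts, INFORMATIVE_CLASSES)
      ntot <- sum(counts)
    } else stop("cannot interpret 'counts'")
  } else stop("cannot interpret 'counts'")
  list(n = as.numeric(n3), total = as.numeric(ntot))
}

#' HYDE estimator of the introgression probability
#'
#' Inverts the mixture of [pattern_probs_mixture()] using observed
#' frequencies:
#' \deqn{\hat\phi = \frac{\hat p_{iijj} - \hat p_{ijij}}
#'                       {\hat p_{iijj} - 2\hat p_{ijij} + \hat p_{ijji}}.}
#' The estimate is flagged invalid when it falls outside (0, 1) or when the
#' denominator is not positive; a zero denominator yields an invalid result,
#' not an error (invalid estimates are tallied, not averaged, in simulation
#' summaries).
#'
#' @param counts a `site_pattern_counts`, a named numeric vector containing
#'   `iijj`, `ijij`, `ijji`, or an unnamed numeric triple in that order
#'   (counts or frequencies).
#' @return list with `phi_hat`, `valid`, and `denominator`.
#' @export
hyde_phi <- function(counts) {
  ic <- .informative_counts(counts)
  if (sum(ic$n) <= 0) stop("total informative weight must be > 0")
  num <- ic$n[1] - ic$n[2]
  den <- ic$n[1] - 2 * ic$n[2] + ic$n[3]
  phi <- if (den == 0) NaN else num / den
  list(phi_hat = phi,
       valid = is.finite(phi) && den > 0 && phi > 0 && phi < 1,
       denominator = den)
}

#' HYDE test of H0: phi = 0 against H1: phi > 0
#'
#' One-sided normal test for the presence of hybridization/introgression
#' from quartet site-pattern counts.  Under the mixture model, phi > 0 if
#' and only if p_iijj > p_ijij, so the test is based on the standardized
#' contrast of those two classes (equivalently, on phi-hat itself when the
#' delta method applies).
#'
#' The standard error depends on what the input carries.  With per-locus
#' subtotals (a [count_patterns()] result over two or more loci) the SE of
#' p_iijj - p_ijij comes from a delete-one-locus jackknife: loci are the
#' independent sampling blocks, and sites within a locus share one
#' genealogy, which overdisperses the pooled counts relative to a
#' multinomial and would otherwise inflate the type-I error.  For plain
#' pooled counts (a numeric vector, sites taken as independent draws) the
#' delta method on phi-hat treating (n_iijj, n_ijij, n_ijji, n_other) as
#' multinomial is used, and when the estimate is invalid (denominator <= 0
#' or phi outside (0,1)) the z falls back to the raw count contrast
#' (n_iijj - n_ijij)/sqrt(n_iijj + n_ijij).
#'
#' @inheritParams hyde_phi
#' @param alpha significance level for the rejection flag.
#' @return an object of class `hyde_result`: `phi_hat`, `valid`, `z`,
#'   `p_value`, `reject`, `alpha`, `counts`, `n`, `se_method`.
#' @export
hyde_test <- function(counts, alpha = 0.05) {
  ic <- .informative_counts(counts)
  est <- hyde_phi(counts)
  n <- ic$total
  p <- ic$n / n
  per_locus <- if (inherits(counts, "site_pattern_counts") &&
                     nrow(counts$per_locus) > 1L) counts$per_locus
               else NULL
  if (!is.null(per_locus)) {
    se_method <- "delete-one-locus jackknife"
    a <- per_locus[, "iijj"]; b <- per_locus[, "ijij"]
    tot <- rowSums(per_locus) - per_locus[, "skipped"]
    T_full <- (sum(a) - sum(b)) / sum(tot)
    ok <- (sum(tot) - tot) > 0
    Tj <- ((sum(a) - a[ok]) - (sum(b) - b[ok])) / (sum(tot) - tot[ok])
    Lj <- length(Tj)
    v <- if (Lj > 1) (Lj - 1) / Lj * sum((Tj - mean(Tj))^2) else NA_real_
    z <- if (isTRUE(v > 0)) T_full / sqrt(v)
         else if (T_full == 0) 0 else sign(T_full) * Inf
  } else if (est$valid) {
    se_method <- "multinomial delta method"
    num <- p[1] - p[2]
    den <- p[1] - 2 * p[2] + p[3]
    g <- c((den - num) / den^2,          # d/dp_iijj
           (-den + 2 * num) / den^2,     # d/dp_ijij
           -num / den^2)                 # d/dp_ijji
    Sigma <- (diag(p) - tcrossprod(p)) / n
    v <- drop(t(g) %*% Sigma %*% g)
    z <- if (v > 0) est$phi_hat / sqrt(v) else Inf
  } else {
    se_method <- "raw count contrast"
    s <- ic$n[1] + ic$n[2]
    z <- if (s > 0) (ic$n[1] - ic$n[2]) / sqrt(s) else 0
  }
  pval <- stats::pnorm(z, lower.tail = FALSE)
  structure(list(phi_hat = est$phi_hat, valid = est$valid, z = z,
                 p_value = pval, reject = pval < alpha, alpha = alpha,
                 counts = stats::setNames(ic$n, INFORMATIVE_CLASSES),
                 n = n, se_method = se_method),
            class = "hyde_result")
}

#' @export
print.hyde_result <- function(x, ...) {
  cat(sprintf(
    "HYDE test: phi_hat = %.4g (%s), z = %.3f, one-sided p = %.4g%s\n",
    x$phi_hat, if (x$valid) "valid" else "INVALID", x$z, x$p_value,
    if (x$reject) sprintf("  [reject at alpha=%g]", x$alpha) else ""))
  invisible(x)
}

#' ABBA-BABA D-statistic with delete-one-locus jackknife
#'
#' With taxa ordered (P1, P2, P3, O), ABBA sites have P2 = P3 != P1 = O and
#' BABA sites have P1 = P3 != P2 = O;
#' \deqn{D = (n_{ABBA} - n_{BABA}) / (n_{ABBA} + n_{BABA}).}
#' Counts are read from a [count_patterns()] result via the role
#' correspondence (P1, P2, P3, O) = (P1, H, P2, O), under which ABBA is the
#' `iijj` class and BABA the `ijij` class of the (O, P1, H, P2) ordering.
#' The standard error is a delete-one-locus jackknife (loci are the
#' independent blocks), giving z = D/SE and a two-sided p-value.
#'
#' @param counts a `site_pattern_counts` with per-locus subtotals.
#' @param alpha significance level for the rejection flag.
#' @return an object of class `d_stat_result`: `D`, `se`, `z`, `p_value`,
#'   `reject`, `defined`, `n_abba`, `n_baba`, `scheme`.
#' @export
d_statistic <- function(counts, alpha = 0.05) {
  if (!inherits(counts, "site_pattern_counts"))
    stop("'counts' must come from count_patterns()")
  a <- counts$per_locus[, "iijj"]
  b <- counts$per_locus[, "ijij"]
  nA <- sum(a); nB <- sum(b)
  if (nA + nB == 0) {
    return(structure(list(D = NA_real_, se = NA_real_, z = NA_real_,
                          p_value = NA_real_, reject = FALSE,
                          defined = FALSE, n_abba = nA, n_baba = nB,
                          scheme = "delete-one-locus jackknife"),
                     class = "d_stat_result"))
  }
  D <- (nA - nB) / (nA + nB)
  den_l <- (nA - a) + (nB - b)
  ok <- den_l > 0
  Dj <- ((nA - a[ok]) - (nB - b[ok])) / den_l[ok]
  Lj <- length(Dj)
  se <- if (Lj > 1) sqrt((Lj - 1) / Lj * sum((Dj - mean(Dj))^2))
        else NA_real_
  z <- if (isTRUE(se > 0)) D / se else sign(D) * Inf
  pval <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  structure(list(D = D, se = se, z = z, p_value = pval,
                 reject = isTRUE(pval < alpha), defined = TRUE,
                 n_abba = nA, n_baba = nB,
                 scheme = "delete-one-locus jackknife"),
            class = "d_stat_result")
}

#' @export
print.d_stat_result <- function(x, ...) {
  if (!x$defined) {
    cat("D-statistic undefined: n_ABBA + n_BABA = 0\n")
  } else {
    cat(sprintf("D = %.4f (SE %.4f, %s), z = %.3f, two-sided p = %.4g\n",
                x$D, x$se, x$scheme, x$z, x$p_value))
  }
  invisible(x)
}
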