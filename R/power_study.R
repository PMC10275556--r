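# Replicate simulation experiments: power, false-positive rates, and
# estimator summaries for the quartet tests under different modes of gene
# flow.
#
# The four built-in templates are three-species-plus-outgroup introgression
# scenarios that differ in the mode of gene flow relative to the putative
# hybrid:
#   sister-flow : donor and recipient are sister species; two sequences are
#                 sampled from the recipient so that a quartet can be formed
#                 (P1 and H are the two recipient sequences);
#   outflow     : gene flow from an ingroup species out to a more distantly
#                 related species (the recipient is P2, not H);
#   inflow-asym : gene flow into the hybrid position but with asymmetric
#                 parental divergence times;
#   inflow-sym  : the hybrid-speciation model (introgression time equal to
#                 the hybrid's divergence from P1, equal parental thetas) --
#                 the only template satisfying the site-pattern test's
#                 assumptions.
# Numeric defaults (tau in expected substitutions/site) are fixed at
# realistic values for a shallow mammalian radiation: tau_QR = 0.000417,
# tau_QRD = 0.0007, tau_RU = 0.0029, root tau = 0.005, introgression times
# 0.000337 (ingroup) and 0.000896 (sister), theta = 0.002 everywhere, and
# default introgression probabilities 0.625 (sister) and 0.106 (others).

TEMPLATE_NAMES <- c("sister-flow", "outflow", "inflow-asym", "inflow-sym")

#' Built-in simulation templates
#'
#' Returns the species network, quartet roles, sampling configuration and
#' sequence-to-role map for one of the four canonical gene-flow scenarios
#' (see the package vignette for the rationale behind the numeric values).
#'
#' @param name template name, one of `"sister-flow"`, `"outflow"`,
#'   `"inflow-asym"`, `"inflow-sym"`.
#' @param phi introgression probability; `NULL` takes the template default
#'   (0.625 for sister-flow, 0.106 otherwise).  Use 0 for null (no gene
#'   flow) simulations.
#' @param theta population size used for every population (default 0.002).
#' @return list with `net`, `roles`, `samples`, `sample_map`, `phi`, `name`.
#' @export
template_network <- function(name = TEMPLATE_NAMES, phi = NULL,
                             theta = 0.002) {
  name <- match.arg(name)
  if (name == "sister-flow") {
    if (is.null(phi)) phi <- 0.625
    net <- species_network(
      "((R:0.0029,U:0.0029)RU:0.0021,S:0.005)RUS;",
      theta = theta,
      edges = list(hybrid_edge("U", "R", time = 0.000896, phi = phi,
                               label = "H1")))
    return(list(net = net,
                roles = quartet_roles(O = "S", P1 = "Ub", H = "Ua",
                                      P2 = "R"),
                samples = sample_config(c(U = 2L, R = 1L, S = 1L)),
                sample_map = c("U^1" = "Ua", "U^2" = "Ub",
                               "R^1" = "R", "S^1" = "S"),
                phi = phi, name = name))
  }
  if (is.null(phi)) phi <- 0.106
  base <- "(((Q:0.000417,R:0.000417)QR:0.000283,D:0.0007)QRD:0.0043,S:0.005)QRDS;"
  edge <- switch(name,
    "outflow" = hybrid_edge("D", "Q", time = 0.000337, phi = phi,
                            label = "H1"),
    "inflow-asym" = hybrid_edge("Q", "D", time = 0.000337, phi = phi,
                                label = "H1", theta_donor = theta),
    "inflow-sym" = hybrid_edge("Q", "D", time = 0.000417, phi = phi,
                               label = "H1", theta_donor = theta))
  net <- species_network(base, theta = theta, edges = list(edge))
  list(net = net,
       roles = quartet_roles(O = "S", P1 = "R", H = "Q", P2 = "D"),
       samples = sample_config(c(Q = 1L, R = 1L, D = 1L, S = 1L)),
       sample_map = NULL,
       phi = phi, name = name)
}

#' Configure a replicate simulation experiment
#'
#' @param template a template name (see [template_network()]) or a list with
#'   `net`, `roles`, `samples`, `sample_map` for a custom scenario.
#' @param phi true introgression probability (overrides the template
#'   default; 0 gives a null experiment).
#' @param loci vector of locus counts to run (e.g. `c(500, 2000, 8000)`).
#' @param n_sites sites per locus (default 500).
#' @param replicates replicate datasets per locus count (default 100).
#' @param alpha significance levels at which rejections are tallied.
#' @param seed master seed; every replicate's seed derives from it.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(template, phi = NULL,
                              loci = c(500, 2000, 8000), n_sites = 500,
                              replicates = 100, alpha = c(0.01, 0.05),
                              seed = 1) {
  stopifnot(replicates >= 1, all(alpha > 0), all(alpha < 1),
            all(loci >= 1), n_sites >= 1)
  tm <- if (is.character(template)) template_network(template, phi = phi)
        else template
  if (!is.null(phi) && !is.character(template)) {
    for (k in seq_along(tm$net$edges)) tm$net$edges[[k]]$phi <- phi
    tm$phi <- phi
  }
  validate_network(tm$net, require_theta = TRUE)
  structure(list(net = tm$net, roles = tm$roles, samples = tm$samples,
                 sample_map = tm$sample_map, phi = tm$phi,
                 name = if (!is.null(tm$name)) tm$name else "custom",
                 loci = loci, n_sites = n_sites, replicates = replicates,
                 alpha = alpha, seed = seed),
            class = "experiment_config")
}

#' Summarize introgression-probability estimates
#'
#' Estimates outside (0, 1) (including NaN from a zero denominator) are
#' invalid: they are excluded from the mean/SD but counted in the invalid
#' proportion.
#'
#' @param phi_hats numeric vector of estimates.
#' @return list with `mean`, `sd`, `prop_invalid`, `n_valid`, `n`.
#' @export
summarize_estimates <- function(phi_hats) {
  stopifnot(length(phi_hats) >= 1)
  valid <- is.finite(phi_hats) & phi_hats > 0 & phi_hats < 1
  v <- phi_hats[valid]
  list(mean = if (length(v)) mean(v) else NA_real_,
       sd = if (length(v) > 1) stats::sd(v) else NA_real_,
       prop_invalid = mean(!valid),
       n_valid = sum(valid), n = length(phi_hats))
}

#' Run a replicate simulation experiment
#'
#' For each locus count and each replicate: simulate a multilocus dataset
#' under the configured network, count quartet site patterns, and apply the
#' HYDE test and the D-statistic.  Rejection rates, summaries of the valid
#' phi estimates and the invalid-estimate proportion are tabulated per locus
#' count.  The run is deterministic given the master seed; a failure in one
#' replicate is recorded and does not abort the experiment.
#'
#' @param cfg an [experiment_config()].
#' @param progress if `TRUE`, print a line per locus count.
#' @return an object of class `power_table`: a data frame with one row per
#'   locus count (rejection rate per test and level, mean +/- SD of valid
#'   phi estimates, invalid proportion), with the replicate-level records in
#'   `attr(, "records")`.
#' @export
run_experiment <- function(cfg, progress = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  set.seed(cfg$seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 length(cfg$loci) * cfg$replicates),
                      nrow = cfg$replicates)
  records <- list()
  rows <- list()
  for (li in seq_along(cfg$loci)) {
    L <- cfg$loci[li]
    if (progress) cat(sprintf("[%s] L = %d ...\n", cfg$name, L))
    rec <- data.frame(L = integer(0), replicate = integer(0),
                      phi_hat = numeric(0), valid = logical(0),
                      hyde_p = numeric(0), D = numeric(0),
                      d_p = numeric(0), error = character(0))
    for (r in seq_len(cfg$replicates)) {
      out <- tryCatch({
        ds <- simulate_dataset(cfg$net, cfg$samples, L, cfg$n_sites,
                               seed = rep_seeds[r, li])
        cnt <- count_patterns(ds, cfg$roles, cfg$sample_map)
        ht <- hyde_test(cnt, alpha = min(cfg$alpha))
        dt <- d_statistic(cnt, alpha = min(cfg$alpha))
        data.frame(L = L, replicate = r, phi_hat = ht$phi_hat,
                   valid = ht$valid, hyde_p = ht$p_value, D = dt$D,
                   d_p = dt$p_value, error = NA_character_)
      }, error = function(e)
        data.frame(L = L, replicate = r, phi_hat = NA_real_,
                   valid = NA, hyde_p = NA_real_, D = NA_real_,
                   d_p = NA_real_, error = conditionMessage(e)))
      rec <- rbind(rec, out)
    }
    records[[as.character(L)]] <- rec
    ok <- is.na(rec$error)
    sm <- if (any(ok)) summarize_estimates(rec$phi_hat[ok])
          else list(mean = NA_real_, sd = NA_real_,
                    prop_invalid = NA_real_)
    row <- data.frame(model = cfg$name, phi_true = cfg$phi, L = L,
                      n_replicates = sum(ok))
    for (a in cfg$alpha) {
      row[[sprintf("hyde_rate_%g", a)]] <- mean(rec$hyde_p[ok] < a)
      row[[sprintf("d_rate_%g", a)]] <- mean(rec$d_p[ok] < a,
                                             na.rm = TRUE)
    }
    row$phi_hat_mean <- sm$mean
    row$phi_hat_sd <- sm$sd
    row$prop_invalid <- sm$prop_invalid
    rows[[li]] <- row
  }
  tab <- do.call(rbind, rows)
  attr(tab, "records") <- records
  attr(tab, "config") <- cfg
  class(tab) <- c("power_table", "data.frame")
  tab
}

#' @export
print.power_table <- function(x, digits = 3, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Simulation experiment '%s' (true phi = %g, %d replicates)\n",
              cfg$name, cfg$phi, cfg$replicates))
  y <- x
  attr(y, "records") <- NULL
  attr(y, "config") <- NULL
  class(y) <- "data.frame"
  print(format(y, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Write a power table (and optionally per-replicate records) to disk
#'
#' @param tab a `power_table`; `path` the TSV output file.
#' @param records_path optional JSONL file for replicate-level records.
#' @export
write_power_table <- function(tab, path, records_path = NULL) {
  y <- tab
  attr(y, "records") <- NULL
  attr(y, "config") <- NULL
  class(y) <- "data.frame"
  utils::write.table(y, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(records_path)) {
    con <- file(records_path, "w")
    on.exit(close(con))
    for (rec in attr(tab, "records"))
      for (i in seq_len(nrow(rec)))
        writeLines(jsonlite::toJSON(as.list(rec[i, ]), auto_unbox = TRUE,
                                    digits = NA, na = "null"), con)
  }
  invisible(path)
}
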