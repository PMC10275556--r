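# Quartet site-pattern machinery.
#
# A site pattern is the joint nucleotide configuration at one alignment
# column across a species quartet ordered (O, P1, H, P2).  Patterns are
# reduced to their shape: bases are relabeled i, j, k, l in order of first
# appearance, giving the 15 set partitions of four positions.  The
# parsimony-informative shapes for the hybridization test are iijj
# (O=P1 != H=P2), ijij (O=H != P1=P2) and ijji (O=P2 != P1=H).

# all restricted-growth strings of length 4; "iiii" is reported as "constant"
PATTERN_CLASSES <- c("constant",
                     "iiij", "iiji", "iijj", "iijk",
                     "ijii", "ijij", "ijik", "ijji", "ijjj",
                     "ijjk", "ijki", "ijkj", "ijkk", "ijkl")
INFORMATIVE_CLASSES <- c("iijj", "ijij", "ijji")
.ALL_COUNT_CLASSES <- c(PATTERN_CLASSES, "skipped")

# lookup from the canonical label code l2*100 + l3*10 + l4 to class index
.SHAPE_LUT <- local({
  lut <- integer(300)
  keys <- c(111, 112, 121, 122, 123, 211, 212, 213, 221, 222,
            223, 231, 232, 233, 234)
  lut[keys] <- seq_along(keys)
  lut
})

# vectorized shape index (1..15) for integer base codes 1..4
.shape_index <- function(o, p1, h, p2) {
  l2 <- 1L + (p1 != o)
  l3 <- l2 + 1L
  w <- h == p1; l3[w] <- l2[w]
  l3[h == o] <- 1L
  l4 <- pmax(l2, l3) + 1L
  w <- p2 == h; l4[w] <- l3[w]
  w <- p2 == p1; l4[w] <- l2[w]
  l4[p2 == o] <- 1L
  .SHAPE_LUT[l2 * 100L + l3 * 10L + l4]
}

# symbol -> integer codes: 1..4 ACGT, 5..10 two-state IUPAC, 0 other
.SYMBOL_CODE <- local({
  v <- stats::setNames(integer(0), character(0))
  v[c("A", "C", "G", "T")] <- 1:4
  v[c("R", "Y", "S", "W", "K", "M")] <- 5:10
  v
})
.AMBIG_SPLIT <- list(R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                     W = c("A", "T"), K = c("G", "T"), M = c("A", "C"))

#' Quartet role assignment
#'
#' @param O,P1,H,P2 species (or sequence-group) names for the outgroup, the
#'   first parent, the putative hybrid, and the second parent.
#' @return a named character vector of class `quartet_roles`.
#' @export
quartet_roles <- function(O, P1, H, P2) {
  r <- c(O = O, P1 = P1, H = H, P2 = P2)
  if (anyDuplicated(r)) stop("quartet roles must name four distinct groups")
  structure(r, class = "quartet_roles")
}

#' Classify one quartet site
#'
#' Returns the pattern-class weights for one site observed in role order
#' (O, P1, H, P2).  Unambiguous quartets put weight 1 on a single class
#' (`iijj` if O=P1 != H=P2, `ijij` if O=H != P1=P2, `ijji` if O=P2 != P1=H,
#' `constant` if all equal, otherwise the non-informative shape class).
#' Each two-state IUPAC code is split 0.5/0.5 over its two resolutions,
#' recursively, so a site with k ambiguous symbols distributes weight over
#' up to 2^k resolved patterns.  Symbols outside \{A,C,G,T,R,Y,S,W,K,M\}
#' make the site unscorable: the weight goes to the `skipped` class.
#'
#' @param o,p1,h,p2 single characters (nucleotide or two-state IUPAC code).
#' @return named numeric vector of weights summing to 1.
#' @export
classify_site <- function(o, p1, h, p2) {
  syms <- toupper(c(o, p1, h, p2))
  if (!all(syms %in% names(.SYMBOL_CODE)))
    return(c(skipped = 1))
  # expand ambiguity codes, 0.5 weight per resolution
  quartets <- list(syms)
  weights <- 1
  for (pos in 1:4) {
    need <- vapply(quartets, function(q) q[pos] %in% names(.AMBIG_SPLIT),
                   logical(1))
    if (!any(need)) next
    out_q <- list(); out_w <- numeric(0)
    for (i in seq_along(quartets)) {
      q <- quartets[[i]]
      if (need[i]) {
        for (b in .AMBIG_SPLIT[[q[pos]]]) {
          q2 <- q; q2[pos] <- b
          out_q[[length(out_q) + 1L]] <- q2
          out_w <- c(out_w, weights[i] / 2)
        }
      } else {
        out_q[[length(out_q) + 1L]] <- q
        out_w <- c(out_w, weights[i])
      }
    }
    quartets <- out_q; weights <- out_w
  }
  idx <- vapply(quartets, function(q)
    .shape_index(.SYMBOL_CODE[q[1]], .SYMBOL_CODE[q[2]],
                 .SYMBOL_CODE[q[3]], .SYMBOL_CODE[q[4]]), integer(1))
  w <- vapply(seq_along(PATTERN_CLASSES),
              function(k) sum(weights[idx == k]), numeric(1))
  names(w) <- PATTERN_CLASSES
  w[w > 0]
}

#' Count quartet site patterns across a multilocus dataset
#'
#' Sums [classify_site()] weights over all sites, all loci, and all
#' nO x n1 x nH x n2 combinations of one sequence per quartet role (the
#' multi-sample enumeration used by site-pattern hybridization tests).
#' Per-locus subtotals are retained to support jackknife resampling.
#'
#' @param data a `multilocus_dataset`, or a list of `locus_alignment` /
#'   character matrices (rows = sequences, columns = sites).
#' @param roles a [quartet_roles()] assignment.  Roles refer to entries of
#'   `sample_map`, so two roles may name different sequences of the same
#'   biological species.
#' @param sample_map named character vector mapping sequence labels (row
#'   names of the alignments) to role group names; defaults to the species
#'   part of `species^index` labels.
#' @param on_missing what to do when a locus lacks a sequence for some role:
#'   `"error"` (default) or `"skip"` (locus dropped with a warning).
#' @return an object of class `site_pattern_counts`: `totals` (named weights
#'   for the 15 shape classes plus `skipped`), `per_locus` (matrix, one row
#'   per locus), `n_combinations`, `n_sites_scored`, and `roles`.
#' @export
count_patterns <- function(data, roles, sample_map = NULL,
                           on_missing = c("error", "skip")) {
  on_missing <- match.arg(on_missing)
  loci <- if (inherits(data, "multilocus_dataset")) data$loci else data
  if (!length(loci)) stop("no loci")
  stopifnot(inherits(roles, "quartet_roles") ||
              all(c("O", "P1", "H", "P2") %in% names(roles)))
  all_labels <- unique(unlist(lapply(loci, rownames)))
  if (is.null(sample_map)) {
    sample_map <- stats::setNames(sub("\\^.*$", "", all_labels), all_labels)
  }
  role_seqs <- lapply(roles[c("O", "P1", "H", "P2")], function(g) {
    s <- names(sample_map)[sample_map == g]
    if (!length(s)) stop("no sequences mapped to role group '", g, "'")
    s
  })
  L <- length(loci)
  nclass <- length(.ALL_COUNT_CLASSES)
  per_locus <- matrix(0, L, nclass,
                      dimnames = list(NULL, .ALL_COUNT_CLASSES))
  keep <- rep(TRUE, L)
  # integer-coded sequence rows per locus
  code_row <- function(aln, lab) {
    if (is.character(aln)) {
      v <- unname(.SYMBOL_CODE[toupper(aln[lab, ])])
      v[is.na(v)] <- 0L
      v
    } else as.integer(unclass(aln)[lab, ])
  }
  combos <- as.matrix(expand.grid(role_seqs$O, role_seqs$P1,
                                  role_seqs$H, role_seqs$P2,
                                  stringsAsFactors = FALSE))
  for (l in seq_len(L)) {
    aln <- loci[[l]]
    labs <- rownames(aln)
    if (!all(unlist(role_seqs) %in% labs)) {
      if (on_missing == "error")
        stop("locus ", l, " lacks sequences for some quartet role")
      warning("skipping locus ", l, ": missing role sequences")
      keep[l] <- FALSE
      next
    }
    for (ci in seq_len(nrow(combos))) {
      o <- code_row(aln, combos[ci, 1]); p1 <- code_row(aln, combos[ci, 2])
      h <- code_row(aln, combos[ci, 3]); p2 <- code_row(aln, combos[ci, 4])
      plain <- o <= 4L & p1 <= 4L & h <= 4L & p2 <= 4L &
        o > 0L & p1 > 0L & h > 0L & p2 > 0L
      if (any(plain)) {
        idx <- .shape_index(o[plain], p1[plain], h[plain], p2[plain])
        per_locus[l, seq_len(15)] <- per_locus[l, seq_len(15)] +
          tabulate(idx, nbins = 15L)
      }
      if (!all(plain)) {
        for (s in which(!plain)) {
          sym <- c(o[s], p1[s], h[s], p2[s])
          if (any(sym == 0L)) {
            per_locus[l, "skipped"] <- per_locus[l, "skipped"] + 1
          } else {
            w <- classify_site(names(.SYMBOL_CODE)[match(sym[1],
                                                         .SYMBOL_CODE)],
                               names(.SYMBOL_CODE)[match(sym[2],
                                                         .SYMBOL_CODE)],
                               names(.SYMBOL_CODE)[match(sym[3],
                                                         .SYMBOL_CODE)],
                               names(.SYMBOL_CODE)[match(sym[4],
                                                         .SYMBOL_CODE)])
            per_locus[l, names(w)] <- per_locus[l, names(w)] + w
          }
        }
      }
    }
  }
  per_locus <- per_locus[keep, , drop = FALSE]
  totals <- colSums(per_locus)
  structure(list(totals = totals, per_locus = per_locus,
                 n_combinations = nrow(combos),
                 n_sites_scored = sum(totals) - totals[["skipped"]],
                 roles = roles),
            class = "site_pattern_counts")
}

#' @export
print.site_pattern_counts <- function(x, ...) {
  cat("site_pattern_counts over", nrow(x$per_locus), "loci,",
      x$n_combinations, "quartet combination(s)\n")
  inf <- x$totals[INFORMATIVE_CLASSES]
  cat(sprintf("  n_iijj = %g, n_ijij = %g, n_ijji = %g (skipped %g)\n",
              inf[1], inf[2], inf[3], x$totals[["skipped"]]))
  invisible(x)
}

#' Write site-pattern counts as TSV
#'
#' One row per quartet with a column per pattern class.
#'
#' @param counts a `site_pattern_counts`.
#' @param path output file.
#' @export
write_pattern_counts <- function(counts, path) {
  df <- data.frame(O = counts$roles[["O"]], P1 = counts$roles[["P1"]],
                   H = counts$roles[["H"]], P2 = counts$roles[["P2"]],
                   t(counts$totals), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
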