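#' Sampling configuration for the simulator
#'
#' @param counts named integer vector: number of haploid sequences sampled
#'   per species (zero entries allowed and dropped).
#' @param diploid character vector of species whose haploid sequences are to
#'   be paired into unphased diploid individuals (consecutive haploids merged
#'   per individual); those species must have even counts.
#' @return an object of class `sample_config`.
#' @export
sample_config <- function(counts, diploid = character(0)) {
  if (is.null(names(counts)) || !all(nzchar(names(counts))))
    stop("'counts' must be named by species")
  counts <- counts[counts > 0]
  if (any(counts != round(counts)) || any(counts < 0))
    stop("sample counts must be non-negative integers")
  if (length(bad <- setdiff(diploid, names(counts))))
    stop("diploid species not in counts: ", paste(bad, collapse = ", "))
  if (any(counts[diploid] %% 2 != 0))
    stop("diploid species must have even haploid counts")
  structure(list(counts = as.integer(counts), species = names(counts),
                 diploid = diploid), class = "sample_config")
}

.as_sample_config <- function(samples) {
  if (inherits(samples, "sample_config")) samples
  else sample_config(samples)
}

# ---- compiled simulation plan --------------------------------------------
#
# Populations are branch segments obtained by cutting each branch at the
# hybrid-edge attachment times.  Lineages move between segments at segment
# upper boundaries: to the next segment up the same branch, or (at a
# speciation time) into the parent branch's bottom segment.  A recipient-side
# boundary carries a Bernoulli(phi) rerouting into the donor-side segment
# starting at the same time; the rerouting is applied before the ordinary
# move, which makes the hybrid-speciation limit (attachment at the recipient
# branch's parent age) well defined.

.compile_msci <- function(net, samples) {
  validate_network(net, require_theta = TRUE)
  samples <- .as_sample_config(samples)
  tips <- net$nodes$label[net$nodes$is_tip]
  if (length(bad <- setdiff(samples$species, tips)))
    stop("sampled species not in network: ", paste(bad, collapse = ", "))
  nodes <- net$nodes
  rt <- root_label(net)
  seg <- list()
  add_seg <- function(branch, lo, hi, theta) {
    seg[[length(seg) + 1L]] <<- list(branch = branch, lo = lo, hi = hi,
                                     theta = theta, to = NA_integer_,
                                     phi = NA_real_,
                                     switch_to = NA_integer_,
                                     edge = NA_integer_)
    length(seg)
  }
  # cut points per branch
  cuts <- lapply(stats::setNames(vector("list", nrow(nodes)), nodes$label),
                 function(x) NULL)
  for (k in seq_along(net$edges)) {
    e <- net$edges[[k]]
    rp <- node_age(net, parent_label(net, e$recipient))
    if (e$time < rp)
      cuts[[e$recipient]] <- rbind(cuts[[e$recipient]],
        data.frame(time = e$time, theta = e$theta_recipient))
    cuts[[e$donor]] <- rbind(cuts[[e$donor]],
      data.frame(time = e$time, theta = e$theta_donor))
  }
  for (lab in nodes$label) {
    lo <- node_age(net, lab)
    hi <- if (lab == rt) Inf else node_age(net, parent_label(net, lab))
    cc <- cuts[[lab]]
    th <- unname(net$theta[lab])
    if (is.null(cc)) { add_seg(lab, lo, hi, th); next }
    cc <- cc[order(cc$time), , drop = FALSE]
    bounds <- c(lo, cc$time, hi)
    thetas <- c(th, ifelse(is.na(cc$theta) | net$linked_theta, th, cc$theta))
    for (i in seq_len(length(bounds) - 1L))
      add_seg(lab, bounds[i], bounds[i + 1L], thetas[i])
  }
  branch <- vapply(seg, `[[`, character(1), "branch")
  los <- vapply(seg, `[[`, numeric(1), "lo")
  his <- vapply(seg, `[[`, numeric(1), "hi")
  find_seg <- function(b, lo) which(branch == b & los == lo)[1]
  # link segments upward
  for (i in seq_along(seg)) {
    if (!is.finite(his[i])) next
    nxt <- which(branch == branch[i] & los == his[i])
    if (length(nxt)) { seg[[i]]$to <- nxt[1]; next }
    par <- parent_label(net, branch[i])
    seg[[i]]$to <- find_seg(par, his[i])
  }
  # register hybrid reroutings on the recipient-side segments ending at time
  for (k in seq_along(net$edges)) {
    e <- net$edges[[k]]
    i <- which(branch == e$recipient & his == e$time)
    j <- find_seg(e$donor, e$time)
    stopifnot(length(i) == 1L, !is.na(j))
    seg[[i]]$phi <- e$phi
    seg[[i]]$switch_to <- j
    seg[[i]]$edge <- k
  }
  events <- sort(unique(his[is.finite(his)]))
  tip_seg <- vapply(samples$species, function(sp) find_seg(sp, 0),
                    integer(1))
  list(seg = seg, events = events, samples = samples, tip_seg = tip_seg,
       theta = vapply(seg, `[[`, numeric(1), "theta"),
       hi = his,
       tip_label = unlist(lapply(seq_along(samples$species), function(i)
         paste0(samples$species[i], "^", seq_len(samples$counts[i])))),
       edge_labels = vapply(seq_along(net$edges), function(k) {
         lb <- net$edges[[k]]$label
         if (is.null(lb)) paste0("H", k) else lb
       }, character(1)))
}

# one backward-time MSci genealogy from a compiled plan
.sim_gene_tree <- function(plan) {
  sm <- plan$samples
  n_tip <- sum(sm$counts)
  nn <- 2L * n_tip - 1L
  parent <- integer(nn)
  age <- numeric(nn)
  lin_node <- seq_len(n_tip)
  lin_seg <- rep(plan$tip_seg, sm$counts)
  nxt <- n_tip
  hyb_edge <- integer(0); hyb_node <- integer(0); hyb_sw <- logical(0)
  t_cur <- 0
  theta <- plan$theta
  hi <- plan$hi
  coalesce_until <- function(t_end) {
    repeat {
      if (length(lin_node) == 1L) return()
      tabseg <- unique(lin_seg)
      ks <- tabulate(match(lin_seg, tabseg))
      rates <- ks * (ks - 1) / theta[tabseg]
      R <- sum(rates)
      if (R == 0) { t_cur <<- t_end; return() }
      w <- stats::rexp(1, R)
      if (t_cur + w >= t_end) { t_cur <<- t_end; return() }
      t_cur <<- t_cur + w
      s <- tabseg[sample.int(length(tabseg), 1L, prob = rates)]
      inz <- which(lin_seg == s)
      pick <- inz[sample.int(length(inz), 2L)]
      nxt <<- nxt + 1L
      parent[lin_node[pick]] <<- nxt
      age[nxt] <<- t_cur
      lin_node[pick[1]] <<- nxt
      lin_seg[pick[1]] <<- s
      lin_node <<- lin_node[-pick[2]]
      lin_seg <<- lin_seg[-pick[2]]
    }
  }
  for (ev in plan$events) {
    coalesce_until(ev)
    if (length(lin_node) == 1L) break
    # move lineages whose segment ends here; hybrid rerouting first
    mv <- which(hi[lin_seg] == ev)
    for (i in mv) {
      s <- plan$seg[[lin_seg[i]]]
      if (!is.na(s$phi)) {
        sw <- stats::runif(1) < s$phi
        hyb_edge <- c(hyb_edge, s$edge)
        hyb_node <- c(hyb_node, lin_node[i])
        hyb_sw <- c(hyb_sw, sw)
        lin_seg[i] <- if (sw) s$switch_to else s$to
      } else {
        lin_seg[i] <- s$to
      }
    }
  }
  if (length(lin_node) > 1L) coalesce_until(Inf)
  tr <- list(parent = parent, age = age, tip_label = plan$tip_label,
             n_tip = n_tip,
             hyb = list(edge = plan$edge_labels[hyb_edge],
                        lineage = hyb_node, switched = hyb_sw))
  class(tr) <- "gene_tree"
  tr
}

#' Hybrid-edge path annotations of a gene tree
#'
#' One row per (lineage, hybrid edge) encounter during the backward-time
#' simulation: which gene-tree lineage reached the edge and whether it
#' switched to the donor branch.
#'
#' @param tree a `gene_tree`.
#' @return data frame with columns `edge`, `lineage`, `switched`.
#' @export
hybrid_log <- function(tree) {
  as.data.frame(tree$hyb, stringsAsFactors = FALSE)
}

#' Simulate a gene tree under the MSci model
#'
#' Backward-time multispecies coalescent with introgression: within each
#' population (branch segment) of the species network, k lineages coalesce
#' at rate k(k-1)/theta per unit tau (pairwise rate 2/theta); at a hybrid
#' edge each surviving lineage on the recipient branch independently switches
#' to the donor branch with probability phi; at speciation nodes lineages
#' merge into the parent population, until a single root lineage remains.
#'
#' Randomness is taken from R's global stream; call `set.seed()` for
#' reproducibility.
#'
#' @param net a `species_network` with all thetas set.
#' @param samples a [sample_config()] or a named count vector.
#' @return an object of class `gene_tree`: `parent` (index of each node's
#'   ancestor, 0 for the root), `age` (node ages, tips at 0), `tip_label`
#'   (`species^index`), and the per-lineage hybrid-edge annotations
#'   retrievable with [hybrid_log()].
#' @export
simulate_gene_tree <- function(net, samples) {
  .sim_gene_tree(.compile_msci(net, samples))
}

#' Simulate a batch of independent gene trees
#'
#' Equivalent to repeated [simulate_gene_tree()] calls but compiles the
#' network bookkeeping once, which matters when drawing many small
#' genealogies.
#'
#' @inheritParams simulate_gene_tree
#' @param n number of independent gene trees.
#' @return list of `gene_tree` objects.
#' @export
simulate_gene_trees <- function(net, samples, n) {
  stopifnot(n >= 1)
  plan <- .compile_msci(net, samples)
  lapply(seq_len(n), function(i) .sim_gene_tree(plan))
}

#' @export
print.gene_tree <- function(x, ...) {
  cat("gene_tree with", x$n_tip, "tips; TMRCA =",
      format(max(x$age)), "\n")
  invisible(x)
}

#' Convert a gene tree to an ape phylo object
#'
#' @param x a `gene_tree`.
#' @param ... unused.
#' @return an [ape::phylo] with branch lengths in expected substitutions
#'   per site.
#' @method as.phylo gene_tree
#' @export
as.phylo.gene_tree <- function(x, ...) {
  n <- x$n_tip
  internal <- order(x$age[(n + 1):(2 * n - 1)], decreasing = TRUE) + n
  newid <- integer(2 * n - 1)
  newid[seq_len(n)] <- seq_len(n)
  newid[internal] <- n + seq_len(n - 1)
  child <- which(x$parent > 0)
  edge <- cbind(newid[x$parent[child]], newid[child])
  structure(list(edge = edge,
                 edge.length = x$age[x$parent[child]] - x$age[child],
                 tip.label = x$tip_label, Nnode = n - 1L),
            class = "phylo", order = "unknown")
}

# ---- sequence simulation (JC69) ------------------------------------------

#' Simulate a sequence alignment along a gene tree under JC69
#'
#' Sites are independent and identically distributed; the root state is
#' uniform on \{A,C,G,T\} and along a branch of length d (expected
#' substitutions per site) the Jukes-Cantor transition applies: the state is
#' retained with probability 1/4 + (3/4) exp(-4d/3), otherwise replaced by
#' one of the three other bases uniformly.
#'
#' @param tree a `gene_tree` (or any list with `parent`, `age`, `tip_label`,
#'   `n_tip` components).
#' @param n_sites number of sites (>= 1).
#' @return an object of class `locus_alignment`: an integer matrix (rows =
#'   sequences, columns = sites, values 1..4 coding A,C,G,T) with row names
#'   the tip labels.  See [alignment_strings()] for the character view.
#' @export
simulate_alignment <- function(tree, n_sites) {
  if (n_sites < 1) stop("n_sites must be >= 1")
  n <- tree$n_tip
  nn <- 2L * n - 1L
  states <- matrix(0L, nn, n_sites)
  root <- which(tree$parent == 0)
  ord <- order(tree$age, decreasing = TRUE)  # parents before children
  states[root, ] <- sample.int(4L, n_sites, replace = TRUE)
  for (v in ord) {
    if (v == root) next
    p <- tree$parent[v]
    d <- tree$age[p] - tree$age[v]
    psame <- 0.25 + 0.75 * exp(-4 * d / 3)
    s <- states[p, ]
    mut <- which(stats::runif(n_sites) >= psame)
    if (length(mut))
      s[mut] <- ((s[mut] - 1L +
                    sample.int(3L, length(mut), replace = TRUE)) %% 4L) + 1L
    states[v, ] <- s
  }
  out <- states[seq_len(n), , drop = FALSE]
  rownames(out) <- tree$tip_label
  class(out) <- "locus_alignment"
  out
}

BASES <- c("A", "C", "G", "T")

#' Character view of a locus alignment
#'
#' @param aln a `locus_alignment`.
#' @return named character vector, one string per sequence.
#' @export
alignment_strings <- function(aln) {
  m <- unclass(aln)
  stats::setNames(
    apply(m, 1, function(r) paste0(BASES[r], collapse = "")),
    rownames(m))
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("locus_alignment:", nrow(x), "sequences x", ncol(x), "sites\n")
  invisible(x)
}

#' @export
as.character.locus_alignment <- function(x, ...) alignment_strings(x)

# two-state IUPAC codes for unordered base pairs
IUPAC2 <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

#' Collapse two haploid sequences into an unphased diploid sequence
#'
#' Per site: if the two bases agree, that base; otherwise the two-state IUPAC
#' ambiguity code for the pair (heterozygote).
#'
#' @param seq_a,seq_b equal-length haploid sequences (strings over ACGT, or
#'   character vectors of single bases).
#' @return an unphased genotype sequence in the same form as the input.
#' @export
diploidize <- function(seq_a, seq_b) {
  as_string <- length(seq_a) == 1L && nchar(seq_a[1]) > 1L
  a <- if (as_string) strsplit(seq_a, "")[[1]] else seq_a
  b <- if (as_string) strsplit(seq_b, "")[[1]] else seq_b
  if (length(a) != length(b)) stop("sequences differ in length")
  if (!all(c(a, b) %in% BASES)) stop("sequences must be over A,C,G,T")
  het <- a != b
  out <- a
  if (any(het)) {
    key <- paste0(pmin(a[het], b[het]), pmax(a[het], b[het]))
    out[het] <- IUPAC2[key]
  }
  if (as_string) paste0(out, collapse = "") else out
}

# ---- multilocus datasets --------------------------------------------------

#' Simulate a multilocus dataset under the MSci model
#'
#' Simulates `L` independent loci, each an independent gene tree from
#' [simulate_gene_tree()] plus a JC69 alignment from [simulate_alignment()].
#' Fully reproducible from `(seed, net, samples, L, n_sites)`: a per-locus
#' seed stream is derived deterministically from the master seed, so the
#' dataset does not depend on evaluation order.
#'
#' @param net a `species_network`.
#' @param samples a [sample_config()] or named count vector.
#' @param L number of loci.
#' @param n_sites sites per locus.
#' @param seed master seed (integer).
#' @param keep_trees if `TRUE`, gene trees are retained alongside alignments.
#' @return an object of class `multilocus_dataset`: list with `loci` (list of
#'   `locus_alignment`), optional `trees`, and provenance fields.
#' @export
simulate_dataset <- function(net, samples, L, n_sites, seed,
                             keep_trees = FALSE) {
  stopifnot(L >= 1)
  samples <- .as_sample_config(samples)
  plan <- .compile_msci(net, samples)
  set.seed(seed)
  locus_seeds <- sample.int(.Machine$integer.max - 1L, L)
  loci <- vector("list", L)
  trees <- if (keep_trees) vector("list", L) else NULL
  for (i in seq_len(L)) {
    set.seed(locus_seeds[i])
    tr <- .sim_gene_tree(plan)
    loci[[i]] <- simulate_alignment(tr, n_sites)
    if (keep_trees) trees[[i]] <- tr
  }
  structure(list(loci = loci, trees = trees, L = L, n_sites = n_sites,
                 seed = seed, samples = samples, net = net),
            class = "multilocus_dataset")
}

#' @export
print.multilocus_dataset <- function(x, ...) {
  cat("multilocus_dataset:", x$L, "loci x", x$n_sites,
      "sites;", sum(x$samples$counts), "sequences per locus\n")
  invisible(x)
}

# ---- writers --------------------------------------------------------------

#' Write a multilocus dataset as stacked PHYLIP loci
#'
#' The multi-record PHYLIP dialect used by coalescent MCMC programs: for each
#' locus a header line `n_seq n_sites` followed by one `tag  sequence` line
#' per sequence, loci separated by a blank line.
#'
#' @param ds a `multilocus_dataset`.
#' @param path output file.
#' @export
write_phylip <- function(ds, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (aln in ds$loci) {
    s <- alignment_strings(aln)
    writeLines(sprintf("%d %d", length(s), ds$n_sites), con)
    writeLines(sprintf("%-12s  %s", names(s), s), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Write a multilocus dataset as one FASTA file per locus
#'
#' @param ds a `multilocus_dataset`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix; files are `<prefix><i>.fasta`.
#' @export
write_fasta_loci <- function(ds, dir, prefix = "locus") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(ds$L)
  for (i in seq_len(ds$L)) {
    m <- unclass(ds$loci[[i]])
    chr <- matrix(tolower(BASES)[m], nrow(m), ncol(m),
                  dimnames = list(rownames(m), NULL))
    paths[i] <- file.path(dir, sprintf("%s%d.fasta", prefix, i))
    ape::write.FASTA(ape::as.DNAbin(chr), paths[i])
  }
  invisible(paths)
}

#' Read one-FASTA-per-locus alignments
#'
#' Counterpart of [write_fasta_loci()]: reads every FASTA file in a
#' directory (sorted by name) into character matrices suitable for
#' [count_patterns()].  IUPAC ambiguity codes are preserved as-is.
#'
#' @param dir directory containing `.fasta`/`.fa` files.
#' @return list of character matrices (rows = sequences, columns = sites).
#' @export
read_fasta_loci <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(fasta|fa|fas)$",
                           full.names = TRUE))
  if (!length(files)) stop("no FASTA files in ", dir)
  lapply(files, function(f) {
    x <- ape::read.FASTA(f)
    m <- toupper(as.character(as.matrix(x)))
    rownames(m) <- names(x)
    m
  })
}

#' Write the sequence-tag-to-species map (Imap)
#'
#' Two-column whitespace-delimited table mapping sequence tags
#' (`species^index`) to species names.
#'
#' @param ds a `multilocus_dataset` (or a `sample_config`).
#' @param path output file.
#' @export
write_imap <- function(ds, path) {
  sm <- if (inherits(ds, "multilocus_dataset")) ds$samples
        else .as_sample_config(ds)
  tags <- unlist(lapply(seq_along(sm$species), function(i)
    paste0(sm$species[i], "^", seq_len(sm$counts[i]))))
  sp <- rep(sm$species, sm$counts)
  writeLines(paste(tags, sp, sep = "\t"), path)
  invisible(path)
}
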