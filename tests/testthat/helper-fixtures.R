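# Shared fixtures: small networks and hand-built alignments.

# three species ((A,B),C), internal branch of 0.002 above the AB split
three_species_net <- function(theta = 0.002) {
  species_network("((A:0.001,B:0.001)AB:0.002,C:0.003)ABC;", theta = theta)
}

# two species with a very deep split: two samples from A behave like a
# single panmictic population of size theta
deep_pair_net <- function(theta = 0.002) {
  species_network("(A:0.05,B:0.05)AB;", theta = theta)
}

# quartet tree (((Q,R),D),S) used by the gene-flow templates
quartet_net <- function(theta = 0.002, edges = list()) {
  species_network(
    "(((Q:0.000417,R:0.000417)QR:0.000283,D:0.0007)QRD:0.0043,S:0.005)QRDS;",
    theta = theta, edges = edges)
}

# build a locus_alignment from named equal-length strings (A,C,G,T only)
aln_from_strings <- function(seqs) {
  chars <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  len <- unique(lengths(chars))
  stopifnot(length(len) == 1)
  m <- matrix(0L, length(seqs), len, dimnames = list(names(seqs), NULL))
  for (i in seq_along(chars)) m[i, ] <- match(chars[[i]], c("A","C","G","T"))
  class(m) <- "locus_alignment"
  m
}

# a two-tip gene tree with total tip-to-tip path length d
two_tip_tree <- function(d, labels = c("A^1", "B^1")) {
  structure(list(parent = c(3L, 3L, 0L), age = c(0, 0, d / 2),
                 tip_label = labels, n_tip = 2L,
                 hyb = list(edge = character(0), lineage = integer(0),
                            switched = logical(0))),
            class = "gene_tree")
}

# cherry species pair of a 3-tip gene tree (the pair coalescing first)
first_cherry <- function(tree) {
  kids <- which(tree$parent == tree$n_tip + 1L)
  sort(sub("\\^.*$", "", tree$tip_label[kids[kids <= tree$n_tip]]))
}
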