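# MSci coalescent and JC69 sequence simulator, checked against closed-form
# multispecies-coalescent and Jukes-Cantor expectations.

test_that("pairwise TMRCA within one population averages theta/2", {
  net <- deep_pair_net(theta = 0.002)
  set.seed(101)
  trees <- simulate_gene_trees(net, c(A = 2L), n = 20000)
  tm <- vapply(trees, function(tr) max(tr$age), numeric(1))
  # TMRCA ~ Exp(rate 2/theta): mean theta/2, SD theta/2
  mc_se <- (0.002 / 2) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 0.001), 3 * mc_se)
})

test_that("rooted topology concordance matches 1 - (2/3) exp(-2*dtau/theta)", {
  net <- three_species_net(theta = 0.002)
  set.seed(102)
  trees <- simulate_gene_trees(net, c(A = 1L, B = 1L, C = 1L), n = 20000)
  conc <- vapply(trees, function(tr)
    identical(first_cherry(tr), c("A", "B")), logical(1))
  p_expect <- 1 - (2 / 3) * exp(-2 * 0.002 / 0.002)
  mc_se <- sqrt(p_expect * (1 - p_expect) / length(conc))
  expect_lt(abs(mean(conc) - p_expect), 3 * mc_se)
})

test_that("gene trees are ultrametric with ages increasing rootward", {
  net <- quartet_net(edges = list(hybrid_edge("Q", "D", 0.0003, 0.4)))
  set.seed(103)
  trees <- simulate_gene_trees(net, c(Q = 2L, R = 1L, D = 1L, S = 1L),
                               n = 200)
  for (tr in trees) {
    expect_equal(tr$age[seq_len(tr$n_tip)], rep(0, tr$n_tip))
    kid <- which(tr$parent > 0)
    expect_true(all(tr$age[tr$parent[kid]] >= tr$age[kid]))
    expect_equal(sum(tr$parent == 0), 1L)
  }
})

test_that("a phi = 1 edge reroutes every lineage; phi frequency is
           binomial(phi) across replicates", {
  net1 <- quartet_net(edges = list(hybrid_edge("D", "Q", 0.000337, 1)))
  set.seed(104)
  trees <- simulate_gene_trees(net1, c(Q = 1L, R = 1L, D = 1L, S = 1L),
                               n = 200)
  sw <- unlist(lapply(trees, function(tr) tr$hyb$switched))
  expect_gt(length(sw), 0)
  expect_true(all(sw))
  # a single D lineage reaches the edge per locus: switch rate ~ Bin(phi)
  net2 <- quartet_net(edges = list(hybrid_edge("D", "Q", 0.000337, 0.3)))
  trees <- simulate_gene_trees(net2, c(Q = 1L, R = 1L, D = 1L, S = 1L),
                               n = 4000)
  sw <- unlist(lapply(trees, function(tr) tr$hyb$switched))
  expect_equal(length(sw), 4000L)
  mc_se <- sqrt(0.3 * 0.7 / 4000)
  expect_lt(abs(mean(sw) - 0.3), 3 * mc_se)
})

test_that("with all phi = 0 the hybrid edge never fires and topology
           frequencies match the plain MSC", {
  net <- species_network("((A:0.001,B:0.001)AB:0.002,C:0.003)ABC;",
                         theta = 0.002,
                         edges = list(hybrid_edge("A", "B", 5e-4, 0)))
  set.seed(105)
  trees <- simulate_gene_trees(net, c(A = 1L, B = 1L, C = 1L), n = 20000)
  expect_false(any(unlist(lapply(trees, function(tr) tr$hyb$switched))))
  conc <- vapply(trees, function(tr)
    identical(first_cherry(tr), c("A", "B")), logical(1))
  p_expect <- 1 - (2 / 3) * exp(-2 * 0.002 / 0.002)
  expect_lt(abs(mean(conc) - p_expect),
            3 * sqrt(p_expect * (1 - p_expect) / length(conc)))
})

test_that("sampling a species absent from the network is an error", {
  expect_error(simulate_gene_tree(three_species_net(), c(A = 1L, X = 1L)),
               "not in network")
})

# ---- JC69 ----------------------------------------------------------------

test_that("JC69 pairwise difference fraction follows (3/4)(1-exp(-4d/3))", {
  set.seed(106)
  aln <- simulate_alignment(two_tip_tree(0.1), 1e5)
  pdiff <- mean(aln[1, ] != aln[2, ])
  p_expect <- 0.75 * (1 - exp(-4 * 0.1 / 3))
  mc_se <- sqrt(p_expect * (1 - p_expect) / 1e5)
  expect_lt(abs(pdiff - p_expect), 3 * mc_se)
})

test_that("JC69 limits: identical sequences at d = 0, saturation at 3/4", {
  set.seed(107)
  a0 <- simulate_alignment(two_tip_tree(0), 2000)
  expect_equal(a0[1, ], a0[2, ])
  asat <- simulate_alignment(two_tip_tree(20), 5e4)
  psat <- mean(asat[1, ] != asat[2, ])
  expect_lt(abs(psat - 0.75), 3 * sqrt(0.75 * 0.25 / 5e4))
})

test_that("simulated base composition is uniform (JC69 stationarity)", {
  set.seed(108)
  aln <- simulate_alignment(two_tip_tree(0.05), 5e4)
  freqs <- tabulate(as.vector(unclass(aln)), 4) / (2 * 5e4)
  expect_true(all(abs(freqs - 0.25) < 3 * sqrt(0.25 * 0.75 / 1e5)))
})

# ---- diploid collapsing ---------------------------------------------------

test_that("diploidize applies two-state IUPAC codes per site", {
  expect_equal(diploidize("AC", "AT"), "AY")
  expect_equal(diploidize("AAAA", "AAAA"), "AAAA")
  expect_equal(diploidize("AG", "GA"), "RR")
  expect_equal(diploidize(c("A", "C"), c("G", "C")), c("R", "C"))
  expect_error(diploidize("AC", "A"), "length")
})

test_that("sample_config enforces diploid pairing and positive counts", {
  sc <- sample_config(c(U = 2L, R = 1L), diploid = "U")
  expect_s3_class(sc, "sample_config")
  expect_error(sample_config(c(U = 3L), diploid = "U"), "even")
  expect_error(sample_config(c(2, 1)), "named")
})

# ---- dataset reproducibility and writers ----------------------------------

test_that("datasets are byte-identical under a fixed seed and differ
           across seeds", {
  net <- three_species_net()
  ds1 <- simulate_dataset(net, c(A = 1L, B = 1L, C = 1L), L = 12,
                          n_sites = 60, seed = 99)
  ds2 <- simulate_dataset(net, c(A = 1L, B = 1L, C = 1L), L = 12,
                          n_sites = 60, seed = 99)
  expect_identical(lapply(ds1$loci, unclass), lapply(ds2$loci, unclass))
  ds3 <- simulate_dataset(net, c(A = 1L, B = 1L, C = 1L), L = 12,
                          n_sites = 60, seed = 100)
  expect_false(identical(lapply(ds1$loci, unclass),
                         lapply(ds3$loci, unclass)))
  expect_length(ds1$loci, 12)
  expect_true(all(vapply(ds1$loci, ncol, 0L) == 60))
})

test_that("PHYLIP/FASTA/Imap writers emit readable files", {
  net <- three_species_net()
  ds <- simulate_dataset(net, c(A = 2L, B = 1L, C = 1L), L = 3,
                         n_sites = 40, seed = 5)
  pf <- tempfile(fileext = ".txt")
  write_phylip(ds, pf)
  lines <- readLines(pf)
  expect_equal(sum(grepl("^4 40$", lines)), 3L)
  dir <- tempfile()
  paths <- write_fasta_loci(ds, dir)
  expect_length(paths, 3)
  back <- ape::read.FASTA(paths[1])
  expect_setequal(names(back), ds$samples |> (\(s)
    unlist(lapply(seq_along(s$species), function(i)
      paste0(s$species[i], "^", seq_len(s$counts[i])))))())
  expect_equal(toupper(unname(vapply(as.character(back), paste0,
                                     "", collapse = ""))),
               unname(alignment_strings(ds$loci[[1]])))
  im <- tempfile()
  write_imap(ds, im)
  imap <- read.table(im, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(imap$V2, c("A", "A", "B", "C"))
  # FASTA reader restores matrices count_patterns can consume
  loci <- read_fasta_loci(dir)
  expect_length(loci, 3)
  expect_equal(loci[[1]]["A^1", ],
               strsplit(alignment_strings(ds$loci[[1]])[["A^1"]], "")[[1]])
})

test_that("gene trees convert to valid ape phylo objects", {
  set.seed(109)
  tr <- simulate_gene_tree(three_species_net(),
                           c(A = 2L, B = 1L, C = 1L))
  ph <- ape::as.phylo(tr)
  expect_s3_class(ph, "phylo")
  expect_equal(ape::Ntip(ph), 4L)
  expect_true(ape::is.ultrametric(ph, tol = 1e-10))
  expect_equal(max(ape::node.depth.edgelength(ph)), max(tr$age))
})
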