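# Species-network representation, parsing, serialization and the
# structural checks behind the quartet hybridization test.

test_that("a simple tree with one introgression edge builds and validates", {
  net <- species_network("((R:0.001,U:0.001)RU:0.002,S:0.003)RUS;",
                         theta = 0.002,
                         edges = list(hybrid_edge("U", "R", 5e-4, 0.3)))
  expect_s3_class(net, "species_network")
  expect_length(net$edges, 1)
  expect_equal(sort(net$nodes$label[net$nodes$is_tip]), c("R", "S", "U"))
  expect_equal(node_age <- net$nodes$age[net$nodes$label == "RU"], 0.001)
})

test_that("invariant violations are rejected with informative errors", {
  mk <- function(...) species_network(
    "((R:0.001,U:0.001)RU:0.002,S:0.003)RUS;", theta = 0.002,
    edges = list(hybrid_edge(...)))
  expect_error(mk("U", "R", 5e-4, 1.2), "phi out of range")
  expect_error(mk("U", "R", 2e-3, 0.3), "recipient branch interval")
  expect_error(mk("RU", "R", 1.5e-3, 0.3), "donor branch interval")
  expect_error(mk("U", "U", 5e-4, 0.3), "must differ")
  expect_error(species_network("((R:0.001,U:0.001):0.002,S:0.003);",
                               theta = -1), "theta")
})

test_that("the outflow quartet is expressible: Q -> D edge on 4 tips", {
  net <- quartet_net(edges = list(hybrid_edge("D", "Q", 0.000337, 0.106)))
  expect_equal(sum(net$nodes$is_tip), 4L)
  expect_equal(net$edges[[1]]$recipient, "D")
  expect_equal(net$edges[[1]]$donor, "Q")
})

test_that("extended-Newick serialization round-trips structurally", {
  net <- quartet_net(edges = list(hybrid_edge("D", "Q", 0.000337, 0.106,
                                              label = "H1")))
  txt <- write_enewick(net)
  expect_match(txt, "#H1")
  net2 <- parse_enewick(txt, theta = 0.002)
  expect_setequal(net2$nodes$label, net$nodes$label)
  ord <- match(net$nodes$label, net2$nodes$label)
  expect_equal(net2$nodes$age[ord], net$nodes$age, tolerance = 1e-9)
  expect_equal(net2$nodes$parent[ord], net$nodes$parent)
  e1 <- net$edges[[1]]; e2 <- net2$edges[[1]]
  expect_equal(e2$recipient, e1$recipient)
  expect_equal(e2$donor, e1$donor)
  expect_equal(e2$time, e1$time, tolerance = 1e-9)
  expect_equal(e2$phi, e1$phi, tolerance = 1e-9)
})

test_that("serialize-then-parse is the identity on random valid networks", {
  set.seed(7)
  for (rep in 1:20) {
    ntip <- sample(4:7, 1)
    tr <- ape::rcoal(ntip, tip.label = paste0("t", seq_len(ntip)))
    net <- species_network(tr, theta = 0.01)
    # pick a donor/recipient tip pair with non-sister parents where possible
    tips <- net$nodes$label[net$nodes$is_tip]
    pair <- sample(tips, 2)
    tmax <- min(node_age <- vapply(pair, function(p)
      net$nodes$age[net$nodes$label ==
                      net$nodes$parent[net$nodes$label == p]], 0))
    e <- hybrid_edge(pair[1], pair[2], time = 0.5 * tmax,
                     phi = runif(1), label = "H1")
    net <- species_network(tr, theta = 0.01, edges = list(e))
    net2 <- parse_enewick(write_enewick(net), theta = 0.01)
    ord <- match(net$nodes$label, net2$nodes$label)
    expect_equal(net2$nodes$age[ord], net$nodes$age, tolerance = 1e-8)
    expect_equal(net2$nodes$parent[ord], net$nodes$parent)
    expect_equal(net2$edges[[1]]$time, e$time, tolerance = 1e-8)
    expect_equal(net2$edges[[1]]$phi, e$phi, tolerance = 1e-8)
  }
})

test_that("malformed extended Newick is rejected, naming the problem", {
  expect_error(parse_enewick("((A:1,B:1):1,C:2;"), "parse error")
  expect_error(parse_enewick("((A:1,(B:0.4)#H1:0.6):1,C:2);"),
               "exactly twice")
  # inconsistent ages at the hybrid tag: the two paths to #H1 disagree
  bad <- "((A:1,(B:0.4)#H1:0.6):1,(#H1:0.9::0.1,C:1.2):0.8);"
  expect_error(parse_enewick(bad), "inconsistent ages")
})

test_that("theta sidecar table and edge JSON round-trip", {
  net <- quartet_net(edges = list(hybrid_edge("D", "Q", 0.000337, 0.106,
                                              label = "H1")))
  tf <- tempfile(fileext = ".tsv")
  write_theta_table(net, tf)
  th <- read_theta_table(tf)
  expect_equal(th, net$theta)
  jf <- tempfile(fileext = ".json")
  write_edges_json(net$edges, jf)
  e2 <- read_edges_json(jf)
  expect_equal(e2[[1]]$recipient, "D")
  expect_equal(e2[[1]]$time, 0.000337)
  expect_equal(e2[[1]]$phi, 0.106)
})

# ---- HYDE structural assumptions -----------------------------------------

test_that("the symmetric inflow (hybrid-speciation) model passes all
           assumption checks", {
  net <- quartet_net(edges = list(
    hybrid_edge("Q", "D", 0.000417, 0.106, theta_donor = 0.002)))
  rep <- check_hyde_assumptions(
    net, quartet_roles(O = "S", P1 = "R", H = "Q", P2 = "D"))
  expect_true(rep$inflow)
  expect_true(rep$nonsister)
  expect_true(rep$tau_symmetric)
  expect_true(rep$theta_symmetric)
  expect_true(rep$valid)
  expect_equal(rep$diagnostics$rate_time_S, rep$diagnostics$rate_time_T)
})

test_that("outflow violates the direction assumption", {
  net <- quartet_net(edges = list(hybrid_edge("D", "Q", 0.000337, 0.106)))
  rep <- check_hyde_assumptions(
    net, quartet_roles(O = "S", P1 = "R", H = "Q", P2 = "D"))
  expect_false(rep$inflow)
  expect_false(rep$valid)
})

test_that("gene flow between sister lineages raises the nonsister flag", {
  net <- quartet_net(edges = list(hybrid_edge("Q", "R", 0.0002, 0.625)))
  rep <- check_hyde_assumptions(
    net, quartet_roles(O = "S", P1 = "R", H = "Q", P2 = "D"))
  expect_false(rep$nonsister)
  expect_false(rep$valid)
})

test_that("asymmetric inflow fails only the symmetry conditions", {
  net <- quartet_net(edges = list(
    hybrid_edge("Q", "D", 0.000337, 0.106, theta_donor = 0.002)))
  rep <- check_hyde_assumptions(
    net, quartet_roles(O = "S", P1 = "R", H = "Q", P2 = "D"))
  expect_true(rep$inflow)
  expect_true(rep$nonsister)
  expect_false(rep$tau_symmetric)
  expect_false(rep$valid)
  # coalescent opportunity is larger on the donor-side branch here
  expect_gt(rep$diagnostics$rate_time_T, rep$diagnostics$rate_time_S)
})

test_that("assumption checking is invariant to a role-preserving
           relabeling", {
  mk <- function(labs) {
    txt <- sprintf(
      "(((%s:0.000417,%s:0.000417)QR:0.000283,%s:0.0007)QRD:0.0043,%s:0.005)RT;",
      labs[1], labs[2], labs[3], labs[4])
    species_network(txt, theta = 0.002, edges = list(
      hybrid_edge(labs[1], labs[3], 0.000417, 0.106, theta_donor = 0.002)))
  }
  r1 <- check_hyde_assumptions(mk(c("Q", "R", "D", "S")),
    quartet_roles(O = "S", P1 = "R", H = "Q", P2 = "D"))
  r2 <- check_hyde_assumptions(mk(c("hyb", "sis", "don", "out")),
    quartet_roles(O = "out", P1 = "sis", H = "hyb", P2 = "don"))
  for (f in c("nonsister", "inflow", "tau_symmetric", "theta_symmetric",
              "valid"))
    expect_identical(r1[[f]], r2[[f]])
})

test_that("bad role assignments are argument errors", {
  net <- quartet_net(edges = list(hybrid_edge("Q", "D", 0.000337, 0.106)))
  expect_error(check_hyde_assumptions(
    net, quartet_roles(O = "S", P1 = "R", H = "QR", P2 = "D")), "tips")
  expect_error(check_hyde_assumptions(
    net, c(O = "S", P1 = "R", H = "Q")), "roles")
})

# ---- rescaling and branch merging ----------------------------------------

test_that("calibration rescales ages linearly, preserving ratios", {
  net <- three_species_net()
  abs_ages <- rescale_to_absolute(net, "ABC", 7e6)
  expect_equal(unname(abs_ages["ABC"]), 7e6)
  expect_equal(unname(abs_ages["AB"]), 7e6 / 3)   # 0.001 / 0.003
  expect_equal(unname(abs_ages[c("A", "B", "C")]), c(0, 0, 0))
  # calibrating a node to its own tau is the identity
  ident <- rescale_to_absolute(net, "AB", 0.001)
  expect_equal(ident, setNames(net$nodes$age, net$nodes$label))
  # ratios preserved exactly under any calibration value
  r <- rescale_to_absolute(net, "ABC", 123.4)
  expect_equal(unname(r["AB"] / r["ABC"]), 0.001 / 0.003)
  expect_error(rescale_to_absolute(net, "A", 7e6), "tau = 0")
})

test_that("merged-branch theta is the branch-length-weighted average", {
  expect_equal(merged_branch_theta(c(1, 1), c(0.002, 0.004)), 0.003)
  expect_equal(merged_branch_theta(c(3, 1), c(0.002, 0.006)), 0.003)
  expect_equal(merged_branch_theta(2, 0.01), 0.01)
  expect_error(merged_branch_theta(c(0, 0), c(1, 1)))
})
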