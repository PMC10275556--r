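#' Species networks with introgression edges
#'
#' A `species_network` is a rooted ultrametric species tree (tips at age 0,
#' node ages measured backward from the present in expected substitutions per
#' site, the usual tau scale) together with per-branch population size
#' parameters theta (= 4*N*mu, same units) and a list of horizontal hybrid
#' (introgression) edges.  Each hybrid edge reroutes, at a fixed time, every
#' lineage traced backward on the recipient branch to the donor branch with
#' probability phi.
#'
#' Branches are identified by the label of their child node; the root label
#' identifies the population ancestral to the root.  A branch cut by a hybrid
#' edge is split into two segments; the segment above the attachment point may
#' carry its own theta (supplied on the edge), otherwise it inherits the
#' branch theta (the "linked" parameterization).
#'
#' @param tree an [ape::phylo] object or a Newick string.  Must be rooted,
#'   binary or multifurcating, and ultrametric (tips contemporaneous).
#' @param theta numeric vector of population sizes, named by node label
#'   (including the root and internal nodes).  A single unnamed value is
#'   recycled to all branches.  May be `NULL` for a purely structural network
#'   (simulation then requires thetas to be set).
#' @param edges list of [hybrid_edge()] specifications.
#' @param linked_theta logical; if `TRUE` the two segments of a branch cut by
#'   a hybrid edge always share the branch theta and per-edge theta overrides
#'   are disallowed.
#' @return an object of class `species_network` with components `nodes`
#'   (data frame: `label`, `age`, `parent`, `is_tip`), `theta`, `edges` and
#'   `linked_theta`.
#' @examples
#' net <- species_network("((A:0.001,B:0.001)AB:0.002,C:0.003)R;",
#'                        theta = 0.002,
#'                        edges = list(hybrid_edge("A", "B", 5e-4, 0.2)))
#' @seealso [parse_network()], [check_hyde_assumptions()],
#'   [simulate_gene_tree()]
#' @export
species_network <- function(tree, theta = NULL, edges = list(),
                            linked_theta = FALSE) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!inherits(tree, "phylo"))
    stop("'tree' must be a phylo object or a Newick string")
  nodes <- .phylo_to_nodes(tree)
  net <- .assemble_network(nodes, theta, edges, linked_theta)
  validate_network(net)
  net
}

# nodes data frame from an ape phylo: ages from root-to-node path lengths,
# tips forced to age 0 after an ultrametricity check.
.phylo_to_nodes <- function(tree) {
  ntip <- length(tree$tip.label)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; node ages cannot be derived")
  depth <- ape::node.depth.edgelength(tree)
  height <- max(depth[seq_len(ntip)])
  if (height <= 0) stop("tree has zero height")
  tipdev <- abs(depth[seq_len(ntip)] - height)
  if (any(tipdev > 1e-6 * height))
    stop("tree is not ultrametric: tip depths differ")
  nnode <- ntip + tree$Nnode
  age <- height - depth
  age[seq_len(ntip)] <- 0
  lab <- character(nnode)
  lab[seq_len(ntip)] <- tree$tip.label
  if (!is.null(tree$node.label) && all(nzchar(tree$node.label))) {
    lab[(ntip + 1):nnode] <- tree$node.label
  } else {
    lab[(ntip + 1):nnode] <- .auto_node_labels(tree)
  }
  parent <- rep(NA_character_, nnode)
  parent[tree$edge[, 2]] <- lab[tree$edge[, 1]]
  data.frame(label = lab, age = age, parent = parent,
             is_tip = seq_len(nnode) <= ntip,
             stringsAsFactors = FALSE)
}

# internal node labels from concatenated descendant tip labels ("QR", "QRD")
.auto_node_labels <- function(tree) {
  ntip <- length(tree$tip.label)
  labs <- vapply((ntip + 1):(ntip + tree$Nnode), function(i) {
    tips <- ape::extract.clade(tree, i)$tip.label
    paste0(sort(tips), collapse = "")
  }, character(1))
  if (anyDuplicated(labs) || any(nchar(labs) > 16))
    labs <- paste0("n", seq_along(labs))
  labs
}

.assemble_network <- function(nodes, theta, edges, linked_theta) {
  labs <- nodes$label
  if (is.null(theta)) {
    theta <- stats::setNames(rep(NA_real_, length(labs)), labs)
  } else if (length(theta) == 1L && is.null(names(theta))) {
    theta <- stats::setNames(rep(as.numeric(theta), length(labs)), labs)
  } else {
    if (is.null(names(theta)))
      stop("'theta' must be named by node label (or be a single value)")
    miss <- setdiff(labs, names(theta))
    full <- stats::setNames(rep(NA_real_, length(labs)), labs)
    full[intersect(names(theta), labs)] <-
      theta[intersect(names(theta), labs)]
    theta <- full
  }
  edges <- lapply(edges, function(e)
    if (inherits(e, "hybrid_edge")) e else do.call(hybrid_edge, e))
  # snap edge times onto node ages they are numerically meant to hit, so
  # that interval checks and segment bookkeeping can compare exactly
  height <- max(nodes$age)
  if (height > 0) {
    edges <- lapply(edges, function(e) {
      d <- abs(nodes$age - e$time)
      i <- which.min(d)
      if (d[i] <= 1e-9 * height) e$time <- nodes$age[i]
      e
    })
  }
  structure(list(nodes = nodes, theta = theta, edges = edges,
                 linked_theta = isTRUE(linked_theta)),
            class = "species_network")
}

#' Specify a hybrid (introgression) edge
#'
#' A horizontal edge at time `time`: every lineage traced backward on the
#' recipient branch reaching `time` switches to the donor branch with
#' probability `phi`.  The two attachment points share the same time.
#'
#' @param recipient,donor labels of the child nodes of the recipient and
#'   donor branches.
#' @param time attachment time (same units as node ages).  Must lie strictly
#'   inside the donor branch's age interval and inside
#'   `(age(recipient), age(parent(recipient))]`; equality with the recipient
#'   branch's parent age is the hybrid-speciation limit (the rerouting is
#'   applied just before the speciation merge).
#' @param phi introgression probability in \[0, 1\].
#' @param label optional tag used in extended-Newick output (`#H` label).
#' @param theta_recipient,theta_donor optional population sizes for the
#'   branch segments above the attachment points (defaults: the branch
#'   thetas).
#' @export
hybrid_edge <- function(recipient, donor, time, phi, label = NULL,
                        theta_recipient = NA_real_, theta_donor = NA_real_) {
  stopifnot(is.character(recipient), is.character(donor),
            length(recipient) == 1L, length(donor) == 1L)
  structure(list(recipient = recipient, donor = donor,
                 time = as.numeric(time), phi = as.numeric(phi),
                 label = label,
                 theta_recipient = as.numeric(theta_recipient),
                 theta_donor = as.numeric(theta_donor)),
            class = "hybrid_edge")
}

# ---- small accessors ------------------------------------------------------

.node_idx <- function(net, label) {
  i <- match(label, net$nodes$label)
  if (anyNA(i)) stop("unknown node label(s): ",
                     paste(label[is.na(i)], collapse = ", "))
  i
}

node_age <- function(net, label) net$nodes$age[.node_idx(net, label)]

parent_label <- function(net, label) net$nodes$parent[.node_idx(net, label)]

root_label <- function(net) net$nodes$label[is.na(net$nodes$parent)]

#' @export
print.species_network <- function(x, ...) {
  ntip <- sum(x$nodes$is_tip)
  cat("species_network:", ntip, "tips,", nrow(x$nodes) - ntip,
      "internal nodes,", length(x$edges), "hybrid edge(s)\n")
  cat("  tips:", paste(x$nodes$label[x$nodes$is_tip], collapse = ", "), "\n")
  for (e in x$edges)
    cat(sprintf("  edge %s -> %s at time %g, phi = %g\n",
                e$donor, e$recipient, e$time, e$phi))
  invisible(x)
}

# tips descended from (and including) the branch child `label`
descendant_tips <- function(net, label) {
  nodes <- net$nodes
  acc <- label
  repeat {
    kids <- nodes$label[!is.na(nodes$parent) & nodes$parent %in% acc]
    new <- setdiff(kids, acc)
    if (!length(new)) break
    acc <- c(acc, new)
  }
  intersect(acc, nodes$label[nodes$is_tip])
}

# label of the most recent common ancestor of a set of tips
mrca_label <- function(net, tips) {
  paths <- lapply(tips, function(t) {
    p <- t
    while (!is.na(parent_label(net, p[length(p)])))
      p <- c(p, parent_label(net, p[length(p)]))
    p
  })
  common <- Reduce(intersect, paths)
  common[which.min(node_age(net, common))]
}

# ---- validation -----------------------------------------------------------

#' Validate a species network
#'
#' Checks the structural invariants: unique labels, a single root, strictly
#' positive branch durations (parent older than child), tips at age 0,
#' positive thetas where given, phi in \[0, 1\], and hybrid-edge times inside
#' the relevant branch intervals with no two events at the same time.
#'
#' @param net a `species_network`.
#' @param require_theta if `TRUE`, missing (NA) thetas are an error.
#' @return `net`, invisibly; errors describe the violated invariant.
#' @export
validate_network <- function(net, require_theta = FALSE) {
  nodes <- net$nodes
  if (anyDuplicated(nodes$label)) stop("duplicate node labels")
  if (sum(is.na(nodes$parent)) != 1L) stop("network must have a single root")
  if (any(nodes$age[nodes$is_tip] != 0)) stop("tips must be at age 0")
  kid <- !is.na(nodes$parent)
  pa <- nodes$age[match(nodes$parent[kid], nodes$label)]
  if (any(pa <= nodes$age[kid]))
    stop("every parent age must be strictly greater than its child's age")
  th <- net$theta
  if (any(!is.na(th) & th <= 0)) stop("all theta must be > 0")
  if (require_theta && anyNA(th))
    stop("theta missing for: ", paste(names(th)[is.na(th)], collapse = ", "))
  rt <- root_label(net)
  times <- numeric(0)
  for (e in net$edges) {
    if (e$phi < 0 || e$phi > 1)
      stop("phi out of range [0,1]: ", e$phi)
    if (e$recipient == e$donor)
      stop("hybrid edge recipient and donor must differ")
    if (e$recipient == rt || e$donor == rt)
      stop("the root branch cannot carry a hybrid edge")
    ra <- node_age(net, e$recipient)
    rp <- node_age(net, parent_label(net, e$recipient))
    da <- node_age(net, e$donor)
    dp <- node_age(net, parent_label(net, e$donor))
    if (!(e$time > ra && e$time <= rp))
      stop(sprintf(
        "hybrid time %g outside recipient branch interval (%g, %g]",
        e$time, ra, rp))
    if (!(e$time > da && e$time < dp))
      stop(sprintf(
        "hybrid time %g outside donor branch interval (%g, %g)",
        e$time, da, dp))
    # no simultaneous distinct events: a hybrid time may only coincide with
    # the recipient branch's parent age (hybrid-speciation limit)
    clash <- nodes$age[abs(nodes$age - e$time) < .Machine$double.eps * 4]
    if (length(clash) && e$time != rp)
      stop("hybrid edge time coincides with an unrelated node age")
    times <- c(times, e$time)
  }
  if (anyDuplicated(times)) stop("two hybrid edges share the same time")
  invisible(net)
}

# ---- parsing and serialization -------------------------------------------

#' Parse a species network from (extended) Newick
#'
#' Plain Newick strings are read with [ape::read.tree()].  Extended Newick
#' with `#H` hybrid tags is parsed directly: the occurrence of a hybrid node
#' written with its child subtree lies on the recipient branch, the leaf
#' occurrence on the donor branch, and the inheritance probability phi is
#' read from the third colon field of the leaf occurrence
#' (`#H1:length::phi`), the convention emitted by [write_enewick()].
#'
#' @param text Newick or extended-Newick string.
#' @param theta,edges,linked_theta as in [species_network()]; `edges` are
#'   ignored when the text itself carries `#H` tags.
#' @return a validated `species_network`.
#' @export
parse_network <- function(text, theta = NULL, edges = list(),
                          linked_theta = FALSE) {
  if (grepl("#", text, fixed = TRUE)) {
    if (length(edges))
      stop("supply hybrid edges either in the text or as 'edges', not both")
    parse_enewick(text, theta = theta, linked_theta = linked_theta)
  } else {
    species_network(text, theta = theta, edges = edges,
                    linked_theta = linked_theta)
  }
}

#' Serialize a species network to extended Newick
#'
#' Hybrid nodes are emitted twice, following the eNewick convention: once
#' with their child subtree (on the recipient branch) as `(...)#H1:len`, and
#' once as a leaf on the donor branch as `#H1:len::phi`, where the third
#' colon field carries the introgression probability.  Horizontal edges give
#' the leaf occurrence length 0.
#'
#' @param net a `species_network`.
#' @param digits significant digits for branch lengths.
#' @return a single string (with trailing `;`).
#' @export
write_enewick <- function(net, digits = 10) {
  nodes <- net$nodes
  fmt <- function(x) sprintf("%.*g", digits, x)
  # attachment points per branch, sorted by time
  att <- list()
  for (k in seq_along(net$edges)) {
    e <- net$edges[[k]]
    tag <- if (!is.null(e$label)) e$label else paste0("H", k)
    att[[e$recipient]] <- rbind(att[[e$recipient]],
      data.frame(time = e$time, role = "recipient", tag = tag, phi = e$phi))
    att[[e$donor]] <- rbind(att[[e$donor]],
      data.frame(time = e$time, role = "donor", tag = tag, phi = e$phi))
  }
  render_node <- function(lab) {
    kids <- nodes$label[!is.na(nodes$parent) & nodes$parent == lab]
    if (!length(kids)) return(lab)
    paste0("(", paste(vapply(kids, render_branch, character(1)),
                      collapse = ","), ")", lab)
  }
  render_branch <- function(lab) {
    s <- render_node(lab)
    t0 <- nodes$age[match(lab, nodes$label)]
    a <- att[[lab]]
    if (!is.null(a)) {
      a <- a[order(a$time), , drop = FALSE]
      for (i in seq_len(nrow(a))) {
        len <- a$time[i] - t0
        if (a$role[i] == "recipient") {
          s <- paste0("(", s, ":", fmt(len), ")#", a$tag[i])
        } else {
          s <- paste0("(", s, ":", fmt(len), ",#", a$tag[i], ":0::",
                      fmt(a$phi[i]), ")")
        }
        t0 <- a$time[i]
      }
    }
    top <- nodes$age[match(nodes$parent[match(lab, nodes$label)],
                           nodes$label)]
    paste0(s, ":", fmt(top - t0))
  }
  paste0(render_node(root_label(net)), ";")
}

# tokenizer + recursive-descent reader for (extended) Newick
.newick_tokens <- function(text) {
  text <- gsub("[[:space:]]", "", text)
  pat <- "\\(|\\)|,|:|;|[^(),:;]+"
  m <- gregexpr(pat, text)[[1]]
  regmatches(text, list(m))[[1]]
}

#' Parse extended Newick with #H hybrid tags
#'
#' @inheritParams parse_network
#' @param tol relative tolerance for the consistency of the two path ages of
#'   a hybrid node.
#' @return a validated `species_network`.
#' @export
parse_enewick <- function(text, theta = NULL, linked_theta = FALSE,
                          tol = 1e-8) {
  toks <- .newick_tokens(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else ""
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  nodes <- list()   # each: label, children (indices), len, gamma
  new_node <- function(label, children, len, gamma) {
    nodes[[length(nodes) + 1L]] <<- list(label = label, children = children,
                                         len = len, gamma = gamma)
    length(nodes)
  }
  parse_clade <- function() {
    children <- integer(0)
    if (peek() == "(") {
      take()
      repeat {
        children <- c(children, parse_clade())
        t <- take()
        if (t == ")") break
        if (t != ",") stop("parse error near token '", t, "'")
      }
    }
    label <- ""
    if (!peek() %in% c(":", ",", ")", ";", "")) label <- take()
    len <- NA_real_; gamma <- NA_real_
    fields <- character(0)
    while (peek() == ":") {
      take()
      if (peek() %in% c(":", ",", ")", ";")) fields <- c(fields, "")
      else fields <- c(fields, take())
    }
    if (length(fields) >= 1 && nzchar(fields[1])) {
      len <- suppressWarnings(as.numeric(fields[1]))
      if (is.na(len)) stop("parse error: bad branch length '", fields[1], "'")
    }
    if (length(fields) >= 3 && nzchar(fields[3])) {
      gamma <- suppressWarnings(as.numeric(fields[3]))
      if (is.na(gamma)) stop("parse error: bad gamma field '", fields[3], "'")
    }
    new_node(label, children, len, gamma)
  }
  root <- parse_clade()
  if (peek() != ";") stop("parse error: expected ';' near token '",
                          peek(), "'")
  .enewick_build(nodes, root, theta, linked_theta, tol)
}

# assemble the display graph read by parse_enewick into a species_network
.enewick_build <- function(nodes, root, theta, linked_theta, tol) {
  n <- length(nodes)
  lab <- vapply(nodes, `[[`, character(1), "label")
  nkid <- vapply(nodes, function(x) length(x$children), integer(1))
  hyb_tag <- ifelse(grepl("#", lab), sub("^.*#", "", lab), NA_character_)
  # depths from root
  depth <- rep(NA_real_, n)
  depth[root] <- 0
  ord <- root
  i <- 1L
  while (i <= length(ord)) {
    for (k in nodes[[ord[i]]]$children) {
      if (is.na(nodes[[k]]$len))
        stop("parse error: missing branch length above '",
             lab[k], "'")
      depth[k] <- depth[ord[i]] + nodes[[k]]$len
      ord <- c(ord, k)
    }
    i <- i + 1L
  }
  is_hyb_leaf <- !is.na(hyb_tag) & nkid == 0L
  is_hyb_int <- !is.na(hyb_tag) & nkid > 0L
  real_tip <- nkid == 0L & !is_hyb_leaf
  height <- depth[real_tip]
  if (max(height) - min(height) > tol * max(height))
    stop("extended Newick is not ultrametric")
  H <- max(height)
  age <- H - depth
  # pair hybrid occurrences and check age consistency
  tags <- unique(stats::na.omit(hyb_tag))
  parent_of <- rep(NA_integer_, n)
  for (i in seq_len(n)) for (k in nodes[[i]]$children) parent_of[k] <- i
  edges <- list()
  for (tg in tags) {
    occ <- which(hyb_tag == tg)
    if (length(occ) != 2L)
      stop("hybrid tag #", tg, " must occur exactly twice")
    int_occ <- occ[nkid[occ] > 0L]
    leaf_occ <- occ[nkid[occ] == 0L]
    if (length(int_occ) != 1L || length(leaf_occ) != 1L)
      stop("hybrid tag #", tg,
           " needs one subtree occurrence and one leaf occurrence")
    if (abs(age[int_occ] - age[leaf_occ]) > tol * max(H, 1e-12))
      stop("inconsistent ages at hybrid tag #", tg)
    phi <- nodes[[leaf_occ]]$gamma
    if (is.na(phi)) phi <- nodes[[int_occ]]$gamma
    if (is.na(phi))
      stop("missing inheritance probability (':len::phi') for #", tg)
    edges[[tg]] <- list(int_occ = int_occ, leaf_occ = leaf_occ, phi = phi)
  }
  # chain nodes: hybrid occurrences and donor attachment nodes
  att_node <- rep(FALSE, n)
  for (e in edges) att_node[parent_of[e$leaf_occ]] <- TRUE
  chain <- is_hyb_int | is_hyb_leaf | att_node
  if (chain[root]) stop("root cannot be a hybrid or attachment node")
  # first real (non-chain) descendant following non-hybrid-leaf children
  first_real_down <- function(i) {
    while (chain[i]) {
      kids <- setdiff(nodes[[i]]$children, which(is_hyb_leaf))
      if (length(kids) != 1L)
        stop("malformed hybrid chain below '", lab[i], "'")
      i <- kids
    }
    i
  }
  real <- which(!chain & !is_hyb_leaf)
  real_parent <- vapply(real, function(i) {
    p <- parent_of[i]
    while (!is.na(p) && chain[p]) p <- parent_of[p]
    if (is.na(p)) NA_integer_ else p
  }, integer(1))
  rlab <- lab[real]
  blank <- !nzchar(rlab)
  if (any(blank)) {
    auto <- paste0("n", seq_len(sum(blank)))
    # keep tip labels mandatory
    if (any(blank & real_tip[real])) stop("unlabeled tip in Newick text")
    rlab[blank] <- auto
  }
  ndf <- data.frame(label = rlab, age = age[real],
                    parent = rlab[match(real_parent, real)],
                    is_tip = real_tip[real], stringsAsFactors = FALSE)
  ndf$age[ndf$is_tip] <- 0
  hedges <- lapply(names(edges), function(tg) {
    e <- edges[[tg]]
    recip <- rlab[match(first_real_down(nodes[[e$int_occ]]$children[1]),
                        real)]
    don_att <- parent_of[e$leaf_occ]
    dkid <- setdiff(nodes[[don_att]]$children, e$leaf_occ)
    donor <- rlab[match(first_real_down(dkid), real)]
    hybrid_edge(recip, donor, time = age[e$int_occ], phi = e$phi,
                label = tg)
  })
  net <- .assemble_network(ndf, theta, hedges, linked_theta)
  validate_network(net)
  net
}

#' Read/write the sidecar theta table
#'
#' Two-column tab-separated table (`branch`, `theta`), one row per node
#' label, pairing population sizes with a Newick/eNewick topology file.
#'
#' @param net a `species_network`; `path` a file path.
#' @return `read_theta_table` returns a named numeric vector.
#' @export
write_theta_table <- function(net, path) {
  utils::write.table(
    data.frame(branch = names(net$theta), theta = unname(net$theta)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_theta_table
#' @export
read_theta_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df$theta), df$branch)
}

#' Read/write hybrid edges as JSON
#'
#' @param edges list of [hybrid_edge()]; `path` a file path.
#' @export
write_edges_json <- function(edges, path) {
  jsonlite::write_json(lapply(edges, unclass), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_edges_json
#' @export
read_edges_json <- function(path) {
  lapply(jsonlite::read_json(path, simplifyVector = FALSE), function(e) {
    e <- e[!vapply(e, is.null, logical(1))]
    do.call(hybrid_edge, e)
  })
}

# ---- HYDE structural assumptions -----------------------------------------

#' Check HYDE's structural assumptions against a species network
#'
#' HYDE assumes a hybrid-speciation (symmetric inflow) quartet model: the
#' putative hybrid H receives genes from a nonsister lineage (inflow), the
#' hybridization time equals the divergence of H from P1 (tau_S = tau_T), and
#' the two parental populations have equal sizes (theta_S = theta_T).  This
#' function inspects the (single) hybrid edge of `net` relative to a quartet
#' role assignment and reports which assumptions hold.
#'
#' The diagnostic also reports the coalescent rate-time products
#' 2*(tau_R - tau_S)/theta_S and 2*(tau_R - tau_T)/theta_T: equality of the
#' products alone equalizes the probability of coalescence in the two
#' parental populations but not the coalescent times, so full validity
#' requires tau and theta symmetry separately.
#'
#' @param net a `species_network` with exactly one hybrid edge.
#' @param roles named character vector with elements `O`, `P1`, `H`, `P2`
#'   naming four distinct tips (outgroup, first parent, putative hybrid,
#'   second parent).
#' @param tol relative tolerance for the tau/theta symmetry checks (exact
#'   models: keep tight; estimated networks: loosen).
#' @return an object of class `hyde_assumptions`: logical flags `nonsister`,
#'   `inflow`, `tau_symmetric`, `theta_symmetric`, overall `valid`, and a
#'   `diagnostics` list (tau_S, tau_T, theta_S, theta_T, tau_R and the two
#'   rate-time products).
#' @export
check_hyde_assumptions <- function(net, roles, tol = 1e-9) {
  need <- c("O", "P1", "H", "P2")
  if (!all(need %in% names(roles)))
    stop("'roles' must name O, P1, H and P2")
  roles <- roles[need]
  tips <- net$nodes$label[net$nodes$is_tip]
  if (!all(roles %in% tips))
    stop("roles must be tips of the network: ",
         paste(setdiff(roles, tips), collapse = ", "))
  if (anyDuplicated(roles)) stop("roles must name four distinct tips")
  if (length(net$edges) != 1L)
    stop("assumption checking requires exactly one hybrid edge")
  e <- net$edges[[1]]
  recip_tips <- descendant_tips(net, e$recipient)
  donor_tips <- descendant_tips(net, e$donor)
  inflow <- (roles[["H"]] %in% recip_tips) &&
    !(roles[["H"]] %in% donor_tips)
  nonsister <- !identical(parent_label(net, e$recipient),
                          parent_label(net, e$donor))
  node_S <- mrca_label(net, c(roles[["P1"]], roles[["H"]]))
  tau_S <- node_age(net, node_S)
  tau_T <- e$time
  theta_S <- unname(net$theta[node_S])
  theta_T <- if (!is.na(e$theta_donor)) e$theta_donor
             else unname(net$theta[e$donor])
  tau_R <- node_age(net, mrca_label(net, c(roles[["H"]], roles[["P2"]])))
  reltol <- function(a, b) abs(a - b) <= tol * max(abs(a), abs(b), 1e-300)
  tau_sym <- reltol(tau_S, tau_T)
  theta_sym <- !is.na(theta_S) && !is.na(theta_T) &&
    reltol(theta_S, theta_T)
  rate_time_S <- 2 * (tau_R - tau_S) / theta_S
  rate_time_T <- 2 * (tau_R - tau_T) / theta_T
  structure(list(
    nonsister = nonsister, inflow = inflow,
    tau_symmetric = tau_sym, theta_symmetric = theta_sym,
    valid = nonsister && inflow && tau_sym && theta_sym,
    roles = roles,
    diagnostics = list(tau_S = tau_S, tau_T = tau_T,
                       theta_S = theta_S, theta_T = theta_T,
                       tau_R = tau_R,
                       rate_time_S = rate_time_S,
                       rate_time_T = rate_time_T)),
    class = "hyde_assumptions")
}

#' @export
print.hyde_assumptions <- function(x, ...) {
  cat("HYDE structural assumptions for roles (O,P1,H,P2) = (",
      paste(x$roles, collapse = ", "), ")\n", sep = "")
  for (f in c("nonsister", "inflow", "tau_symmetric", "theta_symmetric"))
    cat(sprintf("  %-16s %s\n", f, ifelse(isTRUE(x[[f]]), "yes", "NO")))
  cat("  overall HYDE-valid:", ifelse(isTRUE(x$valid), "yes", "NO"), "\n")
  d <- x$diagnostics
  cat(sprintf("  tau_S=%g tau_T=%g theta_S=%g theta_T=%g\n",
              d$tau_S, d$tau_T, d$theta_S, d$theta_T))
  cat(sprintf("  rate-time products: 2(tauR-tauS)/thetaS=%g, ",
              d$rate_time_S))
  cat(sprintf("2(tauR-tauT)/thetaT=%g\n", d$rate_time_T))
  invisible(x)
}

# ---- time rescaling -------------------------------------------------------

#' Rescale node ages to absolute time using a single calibration
#'
#' Linear rescaling: given an absolute age for one node (e.g. a minimum
#' fossil divergence time for the outgroup), every node age is multiplied by
#' `age_value / tau(node)`.  Age ratios are preserved exactly.
#'
#' @param net a `species_network`.
#' @param node label of the calibrated node (must have tau > 0).
#' @param age_value absolute age assigned to `node` (e.g. years).
#' @return named numeric vector of absolute node ages.
#' @export
rescale_to_absolute <- function(net, node, age_value) {
  tau <- node_age(net, node)
  if (tau == 0) stop("cannot calibrate on a node with tau = 0")
  stats::setNames(net$nodes$age * (age_value / tau), net$nodes$label)
}

#' Weighted-average theta for a merged branch
#'
#' When several branches of a larger tree are merged into a single branch of
#' a reduced tree, the population size of the merged branch is the average of
#' the component thetas weighted by the component branch lengths.
#'
#' @param lengths,thetas numeric vectors of component branch lengths and
#'   population sizes (equal length).
#' @return the weighted-average theta.
#' @export
merged_branch_theta <- function(lengths, thetas) {
  stopifnot(length(lengths) == length(thetas), all(lengths >= 0),
            sum(lengths) > 0)
  sum(lengths * thetas) / sum(lengths)
}
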