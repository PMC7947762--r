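# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: equilibrium concentrations come from a
# bracketing root-finder on the mass-action balance, and tree splits from
# graph traversal after edge removal.

# Bound pigment fraction from the mass-action equilibrium
# (A - ab)(B - ab) = Kd * ab, solved numerically.
oracle_bound_fraction <- function(a_tot, b_tot, kd, s0 = 0, smax = 1) {
  frac <- vapply(a_tot, function(a) {
    if (a == 0) return(0)
    if (kd == 0) return(min(a, b_tot) / b_tot)
    bal <- function(ab) (a - ab) * (b_tot - ab) - kd * ab
    ab <- stats::uniroot(bal, c(0, min(a, b_tot)),
                         tol = .Machine$double.eps^0.75)$root
    ab / b_tot
  }, numeric(1))
  s0 + (smax - s0) * frac
}

# Nontrivial splits of an unrooted tree by deleting each internal edge and
# collecting the tip labels reachable from the child endpoint.
oracle_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  labels <- sort(tree$tip.label)
  ref <- labels[1]
  ntip <- length(labels)
  edges <- tree$edge
  keys <- character(0)
  for (k in seq_len(nrow(edges))) {
    if (edges[k, 2] <= ntip) next  # trivial split
    # adjacency over all edges except k
    adj <- edges[-k, , drop = FALSE]
    reach <- edges[k, 2]
    repeat {
      nb <- unique(c(adj[adj[, 1] %in% reach, 2], adj[adj[, 2] %in% reach, 1]))
      grown <- union(reach, nb)
      if (length(grown) == length(reach)) break
      reach <- grown
    }
    side <- sort(tree$tip.label[reach[reach <= ntip]])
    if (length(side) < 2L || length(side) > ntip - 2L) next
    if (ref %in% side) side <- setdiff(labels, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  sort(unique(keys))
}

oracle_is_monophyletic <- function(tree, taxa) {
  labels <- sort(tree$tip.label)
  ref <- labels[1]
  side <- if (ref %in% taxa) setdiff(labels, taxa) else sort(taxa)
  paste(sort(side), collapse = "|") %in% oracle_bipartitions(tree)
}

# All unrooted binary topologies on the given labels, by recursive
# insertion of each next leaf into every edge of every smaller topology,
# working on bracket strings so no package tree machinery is involved.
oracle_all_topologies <- function(labels, as_phylo = TRUE) {
  stopifnot(length(labels) >= 3L)
  # a tree is a nested list of subtrees; leaves are label strings
  trees <- list(list(labels[1], labels[2], labels[3]))
  insert_everywhere <- function(node, leaf) {
    # returns list of copies of `node` with `leaf` inserted on each edge
    # of the subtree rooted at node (edge above each child)
    out <- list()
    for (j in seq_along(node)) {
      with_here <- node
      with_here[[j]] <- list(node[[j]], leaf)
      out <- c(out, list(with_here))
      if (is.list(node[[j]])) {
        for (sub in insert_everywhere(node[[j]], leaf)) {
          deeper <- node
          deeper[[j]] <- sub
          out <- c(out, list(deeper))
        }
      }
    }
    out
  }
  for (i in seq_along(labels)[-(1:3)]) {
    trees <- unlist(lapply(trees, insert_everywhere, leaf = labels[i]),
                    recursive = FALSE)
  }
  to_newick <- function(node) {
    if (!is.list(node)) return(node)
    paste0("(", paste(vapply(node, to_newick, character(1)),
                      collapse = ","), ")")
  }
  nwk <- vapply(trees, function(tr) paste0(to_newick(tr), ";"), character(1))
  if (!as_phylo) return(nwk)
  lapply(nwk, function(s) ape::read.tree(text = s))
}
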