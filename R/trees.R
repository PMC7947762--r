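#' Nontrivial bipartitions of an unrooted tree
#'
#' Each internal edge of an unrooted tree splits the leaf set in two; the
#' split is canonicalized as the sorted side that does not contain the
#' reference taxon (the alphabetically first leaf label), so identical
#' splits from differently rooted or ordered trees compare equal.
#'
#' @param tree A `phylo` object (rooted input is unrooted first).
#' @return Character vector of canonical split keys (labels joined by
#'   `"|"`), with the underlying label sets in attribute `"sides"`.
#' @export
tree_bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tree <- ape::unroot(tree)
  labels <- sort(tree$tip.label)
  if (any(duplicated(labels))) stop("tip labels must be unique")
  ref <- labels[1]
  ntip <- length(labels)
  nnode <- tree$Nnode
  # accumulate tip sets below each internal node (post-order over edges)
  below <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edges))) {
    p <- edges[k, 1]; ch <- edges[k, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  root <- ntip + 1L
  internal_children <- edges[edges[, 2] > ntip, 2]
  sides <- lapply(internal_children, function(node) {
    s <- below[[node]]
    if (ref %in% s) setdiff(labels, s) else s
  })
  sides <- lapply(sides, sort)
  keep <- vapply(sides, function(s)
    length(s) >= 2L && length(s) <= ntip - 2L, logical(1))
  sides <- unique(sides[keep])
  keys <- vapply(sides, paste, character(1), collapse = "|")
  structure(keys, sides = sides)
}

canonical_split_key <- function(taxa, labels) {
  ref <- sort(labels)[1]
  side <- if (ref %in% taxa) setdiff(labels, taxa) else taxa
  paste(sort(side), collapse = "|")
}

#' Test monophyly of a taxon set on an unrooted tree
#'
#' TRUE when the split `taxa | rest` corresponds to an edge of the
#' unrooted tree, the standard unrooted notion of monophyly used when
#' counting clade support over tree collections.
#'
#' @param tree A `phylo` object.
#' @param taxa Character vector of leaf labels, with
#'   `2 <= length(taxa) <= Ntip - 2`.
#' @return Logical scalar.
#' @export
is_clade_monophyletic <- function(tree, taxa) {
  stopifnot(inherits(tree, "phylo"))
  labels <- tree$tip.label
  unknown <- setdiff(taxa, labels)
  if (length(unknown))
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "))
  if (length(taxa) < 2L || length(taxa) > length(labels) - 2L)
    stop("taxa must leave at least 2 leaves on each side of the split")
  canonical_split_key(taxa, labels) %in% tree_bipartitions(tree)
}

#' Clade frequency over a tree collection
#'
#' Counts in how many trees of a collection a taxon set is monophyletic
#' (e.g. "the clade clusters in 83 out of 100 trees").
#'
#' @param trees A `multiPhylo` object or list of `phylo` trees sharing
#'   one leaf set.
#' @param taxa Character vector of leaf labels.
#' @return List: `count`, `n_trees`, `frequency`.
#' @export
clade_frequency <- function(trees, taxa) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("empty tree set")
  lab0 <- sort(trees[[1]]$tip.label)
  same <- vapply(trees, function(tr)
    identical(sort(tr$tip.label), lab0), logical(1))
  if (!all(same)) stop("all trees must share one leaf label set")
  hit <- vapply(trees, is_clade_monophyletic, logical(1), taxa = taxa)
  list(count = sum(hit), n_trees = length(trees),
       frequency = sum(hit) / length(trees))
}

#' Majority-rule consensus tree
#'
#' Builds the consensus containing exactly the bipartitions present in
#' more than `threshold` of the input trees (strict majority; ties at
#' the threshold are excluded). For `threshold >= 0.5` the retained
#' splits are mutually compatible by construction and assemble into a
#' unique (generally multifurcating) tree; each internal node is
#' annotated with the frequency of its split.
#'
#' @param trees A `multiPhylo` object or list of `phylo` trees over one
#'   leaf set.
#' @param threshold Minimum (exclusive) split frequency, >= 0.5.
#'   Default 0.5.
#' @return A `phylo` tree with split frequencies in `node.label`
#'   (empty at the root), plus attribute `"split_support"`: named numeric
#'   vector of the retained splits' frequencies.
#' @export
majority_rule_consensus <- function(trees, threshold = 0.5) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("empty tree set")
  if (threshold < 0.5) stop("threshold must be >= 0.5")
  labels <- sort(trees[[1]]$tip.label)
  same <- vapply(trees, function(tr)
    identical(sort(tr$tip.label), labels), logical(1))
  if (!all(same)) stop("all trees must share one leaf label set")
  tally <- new.env(parent = emptyenv())
  sides <- new.env(parent = emptyenv())
  for (tr in trees) {
    bp <- tree_bipartitions(tr)
    for (i in seq_along(bp)) {
      k <- bp[i]
      assign(k, (get0(k, tally) %||% 0) + 1, tally)
      if (is.null(get0(k, sides))) assign(k, attr(bp, "sides")[[i]], sides)
    }
  }
  keys <- ls(tally)
  freq <- vapply(keys, get0, numeric(1), envir = tally) / length(trees)
  keep <- freq > threshold
  keys <- keys[keep]; freq <- freq[keep]
  # a retained split is stored as the side away from the reference taxon;
  # those sides are nested or disjoint, so they define a rooted hierarchy
  clades <- lapply(keys, get0, envir = sides)
  ord <- order(vapply(clades, length, integer(1)), decreasing = TRUE)
  clades <- clades[ord]; freq <- freq[ord]; keys <- keys[ord]
  build <- function(items, support) {
    # items: leaves (character scalars wrapped) and sub-newick strings
    paste0("(", paste(items, collapse = ","), ")", support)
  }
  assemble <- function(set, cl_idx) {
    # children: maximal retained clades strictly inside `set`
    used <- rep(FALSE, length(set))
    names(used) <- set
    parts <- character(0)
    for (j in cl_idx) {
      cl <- clades[[j]]
      if (all(cl %in% set) && length(cl) < length(set) && !any(used[cl])) {
        inner <- which(vapply(cl_idx, function(k)
          k != j && all(clades[[k]] %in% cl), logical(1)))
        parts <- c(parts, assemble(cl, cl_idx[inner]))
        used[cl] <- TRUE
      }
    }
    parts <- c(parts, set[!used])
    sup <- if (length(set) == length(labels)) "" else {
      j <- which(vapply(seq_along(clades), function(k)
        setequal(clades[[k]], set), logical(1)))
      format(freq[j[1]], digits = 4)
    }
    build(parts, sup)
  }
  nwk <- paste0(assemble(labels, seq_along(clades)), ";")
  cons <- ape::read.tree(text = nwk)
  attr(cons, "split_support") <- stats::setNames(freq, keys)
  cons
}
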