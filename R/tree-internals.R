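# Shared branch-accumulation machinery for Faith's PD and UniFrac.
#
# For an abundance matrix (samples x leaves) and a rooted tree, computes the
# per-edge total abundance descending through each branch by one postorder
# pass (children accumulate into parents). Degree-2 internal nodes are
# handled naturally, which keeps branch-subdivision invariance exact.

edge_abundance <- function(tree, x) {
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  missing <- setdiff(colnames(x), tr$tip.label)
  if (length(missing) > 0)
    stop("OTUs absent from tree: ", paste(missing, collapse = ", "))
  n_nodes <- ntip + tr$Nnode
  n_samp <- nrow(x)
  node_tot <- matrix(0, n_nodes, n_samp)
  tip_idx <- match(colnames(x), tr$tip.label)
  node_tot[tip_idx, ] <- t(x)
  edges <- tr$edge
  edge_tot <- matrix(0, nrow(edges), n_samp)
  for (e in seq_len(nrow(edges))) {
    child <- edges[e, 2]
    edge_tot[e, ] <- node_tot[child, ]
    node_tot[edges[e, 1], ] <- node_tot[edges[e, 1], ] + node_tot[child, ]
  }
  list(edge_tot = edge_tot,
       lengths = tr$edge.length %||% rep(0, nrow(edges)),
       totals = node_tot[ntip + 1L, ],
       tree = tr)
}

# Prune a tree to the given leaf set (no-op if nothing to drop).
prune_tree <- function(tree, keep) {
  drop <- setdiff(tree$tip.label, keep)
  if (length(drop) == 0) return(tree)
  if (length(keep) < 2)
    stop("cannot prune tree below 2 leaves")
  ape::drop.tip(tree, drop, collapse.singles = FALSE)
}
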