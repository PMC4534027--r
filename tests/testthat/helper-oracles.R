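# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately share no code with the package: leaf
# sets are found by walking up from each tip, sums of squares by explicit
# loops.

# For each edge of a rooted tree, the set of leaf labels descending from it.
edge_leaf_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  sets <- vector("list", nrow(tree$edge))
  for (i in seq_len(ntip)) {
    node <- i
    repeat {
      e <- which(tree$edge[, 2] == node)
      if (length(e) == 0) break
      sets[[e]] <- c(sets[[e]], tree$tip.label[i])
      node <- tree$edge[e, 1]
    }
  }
  sets
}

oracle_unweighted_unifrac <- function(a, b, tree) {
  sets <- edge_leaf_sets(tree)
  len <- tree$edge.length
  uniq <- 0
  either <- 0
  for (e in seq_along(sets)) {
    in_a <- any(sets[[e]] %in% a)
    in_b <- any(sets[[e]] %in% b)
    if (in_a || in_b) either <- either + len[e]
    if (xor(in_a, in_b)) uniq <- uniq + len[e]
  }
  if (either == 0) 0 else uniq / either
}

oracle_weighted_unifrac <- function(abund_a, abund_b, tree) {
  sets <- edge_leaf_sets(tree)
  len <- tree$edge.length
  pa <- abund_a / sum(abund_a)
  pb <- abund_b / sum(abund_b)
  total <- 0
  for (e in seq_along(sets)) {
    wa <- sum(pa[names(pa) %in% sets[[e]]])
    wb <- sum(pb[names(pb) %in% sets[[e]]])
    total <- total + len[e] * abs(wa - wb)
  }
  total
}

oracle_faith_pd <- function(presence, tree) {
  sets <- edge_leaf_sets(tree)
  sum(tree$edge.length[vapply(sets, function(s) any(s %in% presence),
                              logical(1))])
}

# One-way ANOVA mean squares and ICC by explicit loops.
oracle_icc <- function(values, groups) {
  groups <- as.character(groups)
  ids <- unique(groups)
  g <- length(ids)
  n <- length(values)
  grand <- mean(values)
  ssb <- 0
  ssw <- 0
  ng <- numeric(g)
  for (j in seq_len(g)) {
    v <- values[groups == ids[j]]
    ng[j] <- length(v)
    ssb <- ssb + length(v) * (mean(v) - grand)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  msb <- ssb / (g - 1)
  msw <- ssw / (n - g)
  keff <- (n - sum(ng^2) / n) / (g - 1)
  icc <- (msb - msw) / (msb + (keff - 1) * msw)
  list(msb = msb, msw = msw, icc = icc)
}

# PERMANOVA-style SS decomposition by explicit loops.
oracle_dist_r2 <- function(dm, groups) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  ss_total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) ss_total <- ss_total + dm[i, j]^2
  }
  ss_total <- ss_total / n
  ss_within <- 0
  for (gr in unique(groups)) {
    idx <- which(groups == gr)
    if (length(idx) < 2) next
    acc <- 0
    for (a in seq_len(length(idx) - 1)) {
      for (b in (a + 1):length(idx)) acc <- acc + dm[idx[a], idx[b]]^2
    }
    ss_within <- ss_within + acc / length(idx)
  }
  list(ss_total = ss_total, ss_within = ss_within,
       r2 = 1 - ss_within / ss_total)
}

# Random rooted tree plus random communities for oracle comparisons.
random_unifrac_case <- function(seed) {
  set.seed(seed)
  ntip <- sample(3:16, 1)
  tree <- ape::rtree(ntip)
  leaves <- tree$tip.label
  a <- sample(leaves, sample(ntip, 1))
  b <- sample(leaves, sample(ntip, 1))
  wa <- stats::setNames(stats::rgamma(ntip, 1), leaves)
  wb <- stats::setNames(stats::rgamma(ntip, 1), leaves)
  list(tree = tree, a = a, b = b,
       wa = wa / sum(wa), wb = wb / sum(wb))
}

# Insert a degree-2 node halfway along edge e of a phylo tree.
subdivide_edge <- function(tree, e) {
  ntip <- length(tree$tip.label)
  new_node <- ntip + tree$Nnode + 1L
  # renumber: internal node ids above ntip stay; append one node
  parent <- tree$edge[e, 1]
  child <- tree$edge[e, 2]
  len <- tree$edge.length[e]
  tree$edge[e, ] <- c(parent, new_node)
  tree$edge <- rbind(tree$edge, c(new_node, child))
  tree$edge.length[e] <- len / 2
  tree$edge.length <- c(tree$edge.length, len / 2)
  tree$Nnode <- tree$Nnode + 1L
  tree
}
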