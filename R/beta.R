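#' Unweighted UniFrac distance between two communities
#'
#' Fraction of branch length unique to either community: branches leading to
#' leaves of exactly one community, divided by branches leading to leaves of
#' either. Ignores relative abundance.
#'
#' @param presence_a,presence_b Character vectors of present OTU ids; both
#'   must be subsets of the tree leaves and at least one must be non-empty.
#' @param tree Rooted `phylo` tree with branch lengths.
#' @return Distance in \[0, 1\].
#' @export
unweighted_unifrac <- function(presence_a, presence_b, tree) {
  presence_a <- unique(as.character(presence_a))
  presence_b <- unique(as.character(presence_b))
  if (length(presence_a) == 0 && length(presence_b) == 0)
    stop("both communities are empty")
  missing <- setdiff(c(presence_a, presence_b), tree$tip.label)
  if (length(missing) > 0)
    stop("OTUs absent from tree: ", paste(missing, collapse = ", "))
  x <- matrix(0, 2, length(tree$tip.label),
              dimnames = list(c("a", "b"), tree$tip.label))
  x["a", presence_a] <- 1
  x["b", presence_b] <- 1
  ea <- edge_abundance(tree, x)
  in_a <- ea$edge_tot[, 1] > 0
  in_b <- ea$edge_tot[, 2] > 0
  shared_or <- sum(ea$lengths[in_a | in_b])
  if (shared_or == 0) return(0)
  sum(ea$lengths[xor(in_a, in_b)]) / shared_or
}

#' Weighted UniFrac distance between two communities
#'
#' Raw (non-normalized) weighted UniFrac:
#' `sum_e len_e * |P_A(e) - P_B(e)|` where `P_X(e)` is the fraction of
#' community X's abundance descending through branch `e`. With
#' `normalized = TRUE` the raw value is divided by its maximum attainable
#' value `sum_e len_e * (P_A(e) + P_B(e))`.
#'
#' @param abund_a,abund_b Named non-negative numeric vectors of relative
#'   abundances over tree leaves (each summing to 1; they are renormalized
#'   defensively). Abundance on a leaf absent from the tree is an error.
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param normalized Divide by the maximum attainable distance
#'   (default `FALSE`, the classic raw form).
#' @return Weighted UniFrac distance.
#' @export
weighted_unifrac <- function(abund_a, abund_b, tree, normalized = FALSE) {
  for (v in list(abund_a, abund_b)) {
    if (is.null(names(v))) stop("abundance vectors must be named by OTU id")
    if (sum(v) <= 0) stop("abundance vectors must have positive total")
    miss <- setdiff(names(v)[v > 0], tree$tip.label)
    if (length(miss) > 0)
      stop("abundance on leaves absent from tree: ",
           paste(miss, collapse = ", "))
  }
  otus <- union(names(abund_a), names(abund_b))
  x <- matrix(0, 2, length(otus), dimnames = list(c("a", "b"), otus))
  x["a", names(abund_a)] <- abund_a / sum(abund_a)
  x["b", names(abund_b)] <- abund_b / sum(abund_b)
  x <- x[, colnames(x) %in% tree$tip.label, drop = FALSE]
  ea <- edge_abundance(tree, x)
  raw <- sum(ea$lengths * abs(ea$edge_tot[, 1] - ea$edge_tot[, 2]))
  if (!normalized) return(raw)
  denom <- sum(ea$lengths * (ea$edge_tot[, 1] + ea$edge_tot[, 2]))
  if (denom == 0) 0 else raw / denom
}

#' Pairwise UniFrac distance matrix for a count table
#'
#' Rarefies every sample once to a common depth (single draw, seeded
#' substream per sample) and computes all pairwise UniFrac distances by
#' accumulating per-branch descendant abundance in one postorder pass per
#' sample. The tree is pruned to the table's OTU set first. Samples below
#' `depth` are dropped with a warning (recorded in the `"excluded"`
#' attribute).
#'
#' @param counts Integer matrix, samples x OTUs.
#' @param tree Rooted `phylo` tree covering the OTUs.
#' @param kind `"weighted"` or `"unweighted"`.
#' @param depth Rarefaction depth (default 5000); ignored when
#'   `rarefy = FALSE`.
#' @param seed Seed for the rarefaction substreams.
#' @param rarefy Rarefy before computing distances (default `TRUE`).
#' @param normalized For `kind = "weighted"`, use the normalized form.
#' @return A [stats::dist] object labelled by sample id, with attribute
#'   `excluded` listing dropped samples.
#' @export
unifrac_matrix <- function(counts, tree, kind = c("weighted", "unweighted"),
                           depth = 5000, seed = 1, rarefy = TRUE,
                           normalized = FALSE) {
  kind <- match.arg(kind)
  counts <- validate_count_table(counts)
  tree <- prune_tree(tree, colnames(counts))
  excluded <- character(0)
  x <- counts
  if (rarefy) {
    totals <- rowSums(counts)
    drop <- totals < depth
    excluded <- rownames(counts)[drop]
    if (any(drop))
      warning(sum(drop), " sample(s) below depth ", depth,
              " excluded from the distance matrix")
    x <- counts[!drop, , drop = FALSE]
    for (i in seq_len(nrow(x))) {
      x[i, ] <- rarefy_counts(x[i, ], depth,
                              seed = mix_seed(seed, hash_string(rownames(x)[i]), 0))
    }
  }
  if (nrow(x) < 2) stop("need at least 2 samples with sufficient depth")
  ea <- edge_abundance(tree, x)
  len <- ea$lengths
  if (kind == "weighted") {
    p <- sweep(ea$edge_tot, 2, ea$totals, "/")
    d <- stats::dist(t(p * len), method = "manhattan")
    if (normalized) {
      denom_i <- colSums(p * len)
      dm <- as.matrix(d)
      denom <- outer(denom_i, denom_i, "+")
      dm <- ifelse(denom == 0, 0, dm / denom)
      diag(dm) <- 0
      d <- stats::as.dist(dm)
    }
  } else {
    o <- (ea$edge_tot > 0) * 1
    and <- t(o) %*% (o * len)
    tot <- colSums(o * len)
    both <- outer(tot, tot, "+")
    or_mat <- both - and
    xor_mat <- both - 2 * and
    dm <- ifelse(or_mat == 0, 0, xor_mat / or_mat)
    diag(dm) <- 0
    d <- stats::as.dist(dm)
  }
  attr(d, "Labels") <- rownames(x)
  attr(d, "excluded") <- excluded
  d
}

#' Principal coordinates analysis
#'
#' Classical metric scaling: the squared-distance matrix is Gower
#' double-centered and eigendecomposed; coordinates are eigenvectors scaled
#' by the square root of their (positive) eigenvalues. Negative eigenvalues
#' (non-Euclidean distances) are dropped, not corrected, and the proportion
#' of variation explained is taken over positive eigenvalues only. Each axis
#' is oriented so its largest-magnitude coordinate is positive, making
#' outputs reproducible across runs.
#'
#' @param d A [stats::dist] object or symmetric distance matrix.
#' @param n_axes Number of axes to return (default 3); if fewer positive
#'   eigenvalues exist, fewer axes are returned with a warning. Use `Inf`
#'   for all positive axes.
#' @return Object of class `pcoa_result`: `coordinates` (samples x axes),
#'   `eigenvalues` (all, descending), `proportion_explained` (per returned
#'   axis), `n_negative` (count of negative eigenvalues dropped).
#' @export
pcoa <- function(d, n_axes = 3) {
  dm <- as.matrix(d)
  if (nrow(dm) != ncol(dm)) stop("distance matrix must be square")
  n <- nrow(dm)
  a <- -0.5 * dm^2
  rm_ <- rowMeans(a)
  cm_ <- colMeans(a)
  b <- a - outer(rm_, rep(1, n)) - outer(rep(1, n), cm_) + mean(a)
  eg <- eigen((b + t(b)) / 2, symmetric = TRUE)
  vals <- eg$values
  tol <- max(abs(vals), 0) * 1e-10
  pos <- which(vals > tol)
  n_neg <- sum(vals < -tol)
  k <- min(n_axes, length(pos))
  if (is.finite(n_axes) && n_axes > length(pos))
    warning("only ", length(pos), " positive eigenvalues; returning ",
            length(pos), " axes")
  if (k == 0) {
    coords <- matrix(0, n, 0, dimnames = list(rownames(dm), NULL))
    prop <- numeric(0)
  } else {
    idx <- pos[seq_len(k)]
    coords <- eg$vectors[, idx, drop = FALSE] %*%
      diag(sqrt(vals[idx]), k, k)
    # deterministic orientation: largest |coordinate| on each axis positive
    for (j in seq_len(k)) {
      i_max <- which.max(abs(coords[, j]))
      if (coords[i_max, j] < 0) coords[, j] <- -coords[, j]
    }
    rownames(coords) <- rownames(dm)
    colnames(coords) <- paste0("PCoA", seq_len(k))
    prop <- vals[idx] / sum(vals[pos])
  }
  structure(list(coordinates = coords,
                 eigenvalues = vals,
                 proportion_explained = prop,
                 n_negative = n_neg),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("Principal coordinates analysis\n")
  cat(sprintf("  %d samples, %d axes returned (%d negative eigenvalues dropped)\n",
              nrow(x$coordinates), ncol(x$coordinates), x$n_negative))
  if (length(x$proportion_explained) > 0)
    cat("  variation explained:",
        paste(sprintf("%.1f%%", 100 * x$proportion_explained), collapse = ", "),
        "\n")
  invisible(x)
}

#' Distance-based coefficient of determination
#'
#' One-factor PERMANOVA-style decomposition of squared pairwise distances:
#' `ss_total = sum_{i<j} d_ij^2 / N`,
#' `ss_within = sum_g sum_{i<j in g} d_ij^2 / n_g`, and
#' `R^2 = 1 - ss_within / ss_total`, the fraction of overall community
#' variability explained by the grouping (here, typically subjects).
#'
#' @param d A [stats::dist] object or square distance matrix with labels.
#' @param grouping Group label per sample: either a vector aligned with the
#'   distance labels or a named vector keyed by sample id.
#' @return Object of class `dist_r2` with `r2`, `ss_total`, `ss_within`,
#'   `ss_between`, `grouping_name`, `n_groups`.
#' @export
dist_r2 <- function(d, grouping) {
  grouping_name <- deparse(substitute(grouping))
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (!is.null(names(grouping)) && !is.null(rownames(dm))) {
    miss <- setdiff(rownames(dm), names(grouping))
    if (length(miss) > 0)
      stop("samples without group label: ", paste(miss, collapse = ", "))
    grouping <- grouping[rownames(dm)]
  }
  if (length(grouping) != n) stop("grouping length must match sample count")
  if (any(is.na(grouping))) stop("all samples must be labelled")
  grouping <- factor(as.character(grouping))
  if (nlevels(grouping) < 2) stop("need at least 2 groups")
  d2 <- dm^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in levels(grouping)) {
    idx <- which(grouping == g)
    if (length(idx) < 2) next  # singleton groups contribute 0 within-SS
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_between <- ss_total - ss_within
  r2 <- if (ss_total == 0) NA_real_ else 1 - ss_within / ss_total
  structure(list(r2 = r2, ss_total = ss_total, ss_within = ss_within,
                 ss_between = ss_between,
                 grouping_name = grouping_name,
                 n_groups = nlevels(grouping)),
            class = "dist_r2")
}

#' @export
print.dist_r2 <- function(x, ...) {
  cat(sprintf("Distance-based R2 = %.4f (%d groups)\n", x$r2, x$n_groups))
  cat(sprintf("  SS between = %.4g, within = %.4g, total = %.4g\n",
              x$ss_between, x$ss_within, x$ss_total))
  invisible(x)
}
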