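#' Rarefy a count vector to fixed depth
#'
#' Subsamples reads without replacement (multivariate hypergeometric), the
#' standard rarefaction used to compare samples at equal sequencing depth.
#'
#' @param counts Non-negative integer vector of per-OTU read counts.
#' @param depth Target depth; `sum(counts)` must be at least `depth` (no
#'   silent smaller draw is taken).
#' @param seed Optional integer seed.
#' @return Integer vector of the same length, summing exactly to `depth`,
#'   with each entry bounded by the original count.
#' @export
rarefy_counts <- function(counts, depth, seed = NULL) {
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  total <- sum(counts)
  if (total < depth)
    stop(sprintf("sample has %d reads, below rarefaction depth %d", total, depth))
  # expand reads in OTU-name order (when named) so that, for a given seed,
  # the draw does not depend on column order
  ord <- if (!is.null(names(counts))) order(names(counts)) else seq_along(counts)
  out <- with_seed(seed, {
    reads <- rep.int(ord, counts[ord])
    tabulate(reads[sample.int(total, depth)], nbins = length(counts))
  })
  out <- as.integer(out)
  names(out) <- names(counts)
  out
}

#' Observed species richness
#'
#' Number of OTUs with at least one read.
#'
#' @param counts Non-negative count vector.
#' @return Integer richness.
#' @export
observed_species <- function(counts) {
  as.integer(sum(counts > 0))
}

#' Chao1 richness estimator (bias-corrected)
#'
#' `S_obs + F1 * (F1 - 1) / (2 * (F2 + 1))` where `F1` and `F2` are the
#' singleton and doubleton counts. Always at least the observed richness.
#'
#' @param counts Non-negative integer count vector.
#' @return Chao1 estimate.
#' @export
chao1 <- function(counts) {
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Shannon diversity index
#'
#' `H = -sum(p_i * ln(p_i))` over taxa with positive abundance (natural
#' log). Delegates to [vegan::diversity()].
#'
#' @param counts Non-negative count vector with positive total.
#' @return Shannon index.
#' @export
shannon_index <- function(counts) {
  if (sum(counts) <= 0) stop("Shannon index undefined for an all-zero sample")
  as.numeric(vegan::diversity(counts, index = "shannon"))
}

#' Faith's phylogenetic diversity (whole tree)
#'
#' Sum of branch lengths of the minimal subtree connecting the present OTUs
#' to the root (root-inclusive convention, as in the classic QIIME
#' whole-tree PD). With `include_root = FALSE` the branches above the most
#' recent common ancestor of the present leaves are excluded.
#'
#' @param presence Character vector of present OTU ids (must be tree leaves).
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param include_root Include the root connection (default `TRUE`).
#' @return Phylogenetic diversity.
#' @export
faith_pd <- function(presence, tree, include_root = TRUE) {
  presence <- unique(as.character(presence))
  missing <- setdiff(presence, tree$tip.label)
  if (length(missing) > 0)
    stop("OTUs absent from tree: ", paste(missing, collapse = ", "))
  if (length(presence) == 0) return(0)
  x <- matrix(0, 1, length(tree$tip.label),
              dimnames = list("s", tree$tip.label))
  x[1, presence] <- 1
  ea <- edge_abundance(tree, x)
  pd <- sum(ea$lengths[ea$edge_tot[, 1] > 0])
  if (!include_root && length(presence) >= 1) {
    tr <- ea$tree
    ntip <- length(tr$tip.label)
    node <- if (length(presence) == 1) {
      match(presence, tr$tip.label)
    } else {
      ape::getMRCA(tr, presence)
    }
    root <- ntip + 1L
    # walk from the MRCA up to the root, subtracting those branches
    while (node != root) {
      e <- which(tr$edge[, 2] == node)
      pd <- pd - tr$edge.length[e]
      node <- tr$edge[e, 1]
    }
  }
  pd
}

#' Rarefied alpha diversity for a count table
#'
#' For each sample, draws `draws` independent rarefactions of `depth` reads
#' and reports the mean of each requested metric over the draws. Samples
#' with fewer than `depth` total reads are excluded (flagged, with a
#' warning), never silently rarefied to a smaller depth. Each (sample, draw)
#' pair uses its own RNG substream keyed by sample id, so results do not
#' depend on row order.
#'
#' @param counts Integer matrix, samples x OTUs.
#' @param metrics Any of `"observed_species"`, `"chao1"`, `"shannon"`,
#'   `"pd"` (PD requires `tree`).
#' @param tree Rooted `phylo` tree over the OTUs (for `"pd"`).
#' @param depth Rarefaction depth (default 5000 reads).
#' @param draws Number of rarefaction draws (default 20).
#' @param seed Master seed for the rarefaction substreams.
#' @return data.frame with `sample_id`, one column per metric (NA for
#'   excluded samples), `excluded`, and `n_draws`.
#' @export
alpha_diversity <- function(counts,
                            metrics = c("observed_species", "chao1",
                                        "shannon", "pd"),
                            tree = NULL, depth = 5000, draws = 20, seed = 1) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  counts <- validate_count_table(counts)
  if ("pd" %in% metrics && is.null(tree))
    stop("metric 'pd' requires a tree")
  n <- nrow(counts)
  totals <- rowSums(counts)
  excluded <- totals < depth
  if (any(excluded))
    warning(sum(excluded), " sample(s) below rarefaction depth ", depth,
            " excluded: ", paste(rownames(counts)[excluded], collapse = ", "))
  keep <- which(!excluded)
  acc <- matrix(0, n, length(metrics),
                dimnames = list(rownames(counts), metrics))
  if (!is.null(tree)) tree <- prune_tree(tree, colnames(counts))
  for (j in seq_len(draws)) {
    rar <- matrix(0L, length(keep), ncol(counts),
                  dimnames = list(rownames(counts)[keep], colnames(counts)))
    for (ii in seq_along(keep)) {
      i <- keep[ii]
      rar[ii, ] <- rarefy_counts(
        counts[i, ], depth,
        seed = mix_seed(seed, hash_string(rownames(counts)[i]), j)
      )
    }
    if ("observed_species" %in% metrics)
      acc[keep, "observed_species"] <- acc[keep, "observed_species"] +
        rowSums(rar > 0)
    if ("chao1" %in% metrics) {
      f1 <- rowSums(rar == 1)
      f2 <- rowSums(rar == 2)
      acc[keep, "chao1"] <- acc[keep, "chao1"] +
        rowSums(rar > 0) + f1 * (f1 - 1) / (2 * (f2 + 1))
    }
    if ("shannon" %in% metrics)
      acc[keep, "shannon"] <- acc[keep, "shannon"] +
        as.numeric(vegan::diversity(rar, index = "shannon"))
    if ("pd" %in% metrics) {
      ea <- edge_abundance(tree, rar)
      acc[keep, "pd"] <- acc[keep, "pd"] +
        colSums(ea$lengths * (ea$edge_tot > 0))
    }
  }
  res <- as.data.frame(acc / draws)
  res[excluded, ] <- NA_real_
  data.frame(sample_id = rownames(counts), res,
             excluded = excluded, n_draws = ifelse(excluded, 0L, draws),
             row.names = NULL, stringsAsFactors = FALSE)
}
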