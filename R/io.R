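#' Read an OTU count table from TSV
#'
#' Reads a tab-delimited abundance table and returns the package's internal
#' representation: an integer matrix with samples in rows and OTUs in columns.
#' Both common on-disk orientations are supported; the default (`"otus"`)
#' expects OTUs in rows and samples in columns, the usual amplicon-table
#' convention.
#'
#' @param path Path to a tab-delimited file with a header row. The first
#'   column holds row identifiers (OTU ids for `orientation = "otus"`,
#'   sample ids for `orientation = "samples"`).
#' @param orientation Either `"otus"` (OTUs in rows, default) or `"samples"`
#'   (samples in rows).
#' @return Integer matrix (samples x OTUs) with sample ids as row names and
#'   OTU ids as column names.
#' @seealso [write_count_table()], [relative_abundance()]
#' @export
read_count_table <- function(path, orientation = c("otus", "samples")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("count table file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2) stop("count table needs an id column plus >= 1 data column")
  ids <- raw[[1]]
  cols <- colnames(raw)[-1]
  num <- suppressWarnings(
    vapply(raw[-1], function(col) as.numeric(col), numeric(nrow(raw)))
  )
  num <- matrix(num, nrow = nrow(raw), dimnames = list(ids, cols))
  bad <- which(is.na(num) | num < 0 | num != floor(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "count table cell (row '%s', column '%s') is not a non-negative integer: '%s'",
      ids[bad[1, 1]], cols[bad[1, 2]], raw[bad[1, 1], bad[1, 2] + 1]
    ))
  }
  mat <- num
  if (orientation == "otus") mat <- t(mat)
  storage.mode(mat) <- "integer"
  validate_count_table(mat)
}

#' Write an OTU count table to TSV
#'
#' @param counts Integer matrix, samples x OTUs.
#' @param path Output file path.
#' @param orientation On-disk orientation, as in [read_count_table()].
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path, orientation = c("otus", "samples")) {
  orientation <- match.arg(orientation)
  counts <- validate_count_table(counts)
  out <- if (orientation == "otus") t(counts) else counts
  id_name <- if (orientation == "otus") "otu_id" else "sample_id"
  df <- data.frame(id = rownames(out), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a count table
#'
#' Checks the internal samples x OTUs contract: integer, non-negative,
#' unique sample and OTU identifiers.
#'
#' @param counts Matrix to validate.
#' @return The validated integer matrix.
#' @export
validate_count_table <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix (samples x OTUs)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample ids as rownames and OTU ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  counts
}

#' Read sample metadata from TSV
#'
#' The metadata maps each sample to its design cell: subject, collection
#' medium, incubation time before freezing, and technical replicate number.
#'
#' @param path Tab-delimited file with columns `sample_id`, `subject_id`,
#'   `medium`, `time_days`, `replicate`.
#' @return A validated data.frame (one row per sample) with `medium` as a
#'   factor over `none`, `rnalater`, `rnalater_kan`, `rnalater_cipro`.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_sample_metadata(df)
}

#' Validate sample metadata
#'
#' @param meta data.frame with columns `sample_id`, `subject_id`, `medium`,
#'   `time_days`, `replicate`.
#' @return The validated data.frame.
#' @export
validate_sample_metadata <- function(meta) {
  required <- c("sample_id", "subject_id", "medium", "time_days", "replicate")
  missing <- setdiff(required, colnames(meta))
  if (length(missing) > 0)
    stop("metadata missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample ids in metadata")
  unknown <- setdiff(unique(as.character(meta$medium)), MEDIA_LEVELS)
  if (length(unknown) > 0)
    stop("unknown medium values: ", paste(unknown, collapse = ", "))
  meta$medium <- factor(as.character(meta$medium), levels = MEDIA_LEVELS)
  meta$time_days <- as.integer(meta$time_days)
  meta$replicate <- as.integer(meta$replicate)
  if (any(is.na(meta$time_days)) || any(is.na(meta$replicate)))
    stop("time_days and replicate must be integers")
  key <- paste(meta$subject_id, meta$medium, meta$time_days, meta$replicate)
  if (anyDuplicated(key))
    stop("duplicated (subject, medium, time, replicate) design tuple: ",
         key[duplicated(key)][1])
  odd <- meta$medium == "none" & meta$time_days != 0
  if (any(odd))
    warning(sum(odd), " sample(s) with medium 'none' at time > 0; ",
            "the reference design collects no-media aliquots at time 0 only")
  meta
}

#' Write sample metadata to TSV
#'
#' @param meta Metadata data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(meta, path) {
  meta <- validate_sample_metadata(meta)
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an OTU-to-phylum taxonomy map
#'
#' @param path Tab-delimited file with two columns: OTU id and phylum.
#' @return Named character vector mapping OTU id to phylum.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("taxonomy file needs two columns: otu_id, phylum")
  if (anyDuplicated(df[[1]])) stop("duplicate OTU ids in taxonomy map")
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Write a taxonomy map to TSV
#'
#' @param taxonomy Named character vector (OTU id -> phylum).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  df <- data.frame(otu_id = names(taxonomy), phylum = as.character(taxonomy),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse a Newick string into a rooted phylogenetic tree
#'
#' Thin wrapper over [ape::read.tree()] adding the validation this package
#' relies on: unique leaf labels and non-negative branch lengths (missing
#' lengths default to 0). A basal trifurcation is accepted as the root;
#' no re-rooting is attempted.
#'
#' @param text Newick string.
#' @return An [ape] `phylo` object.
#' @export
parse_newick <- function(text) {
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e)),
                   warning = function(w) stop("Newick parse error: ",
                                              conditionMessage(w)))
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("Newick parse error: could not read tree")
  validate_phylo_tree(tree)
}

#' Read a rooted tree from a Newick file
#'
#' @param path Path to a Newick file.
#' @return An [ape] `phylo` object.
#' @export
read_phylo_tree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' Write a tree to a Newick file
#'
#' @param tree `phylo` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_phylo_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Validate a phylogenetic tree
#'
#' @param tree `phylo` object.
#' @return The validated tree; `NULL` edge lengths are replaced by zeros.
#' @export
validate_phylo_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0, nrow(tree$edge))
  if (any(is.na(tree$edge.length)) || any(tree$edge.length < 0))
    stop("all branch lengths must be non-negative")
  tree
}

#' Convert counts to relative abundances
#'
#' Divides each sample row by its total. Rows with zero total reads are left
#' all-zero and reported via the `"zero_rows"` attribute (with a warning),
#' rather than producing NaN.
#'
#' @param counts Numeric matrix, samples x OTUs.
#' @return Numeric matrix of per-sample relative abundances (rows sum to 1,
#'   except flagged zero rows), with attribute `zero_rows`.
#' @export
relative_abundance <- function(counts) {
  totals <- rowSums(counts)
  zero <- totals == 0
  comp <- counts / ifelse(totals == 0, 1, totals)
  comp[zero, ] <- 0
  attr(comp, "zero_rows") <- rownames(counts)[zero]
  if (any(zero))
    warning(sum(zero), " sample(s) with zero total reads left all-zero")
  comp
}

#' Aggregate OTU abundances to phylum level
#'
#' Sums abundance columns by phylum. OTUs missing from the taxonomy map are
#' assigned to `"other"`, so partial maps covering only the major phyla work.
#' Per-sample totals are conserved.
#'
#' @param comp Abundance matrix, samples x OTUs (counts or proportions).
#' @param taxonomy Named character vector, OTU id -> phylum.
#' @return Matrix, samples x phyla (columns sorted alphabetically).
#' @export
aggregate_by_phylum <- function(comp, taxonomy) {
  phyla <- unname(taxonomy[colnames(comp)])
  phyla[is.na(phyla)] <- "other"
  agg <- t(rowsum(t(comp), group = phyla))
  agg[, order(colnames(agg)), drop = FALSE]
}
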