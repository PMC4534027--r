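# Report orchestration: the 14-metric reproducibility and stability tables,
# the media composition comparison, and the abundance-reproducibility trend.

METRIC_ROWS <- c(MAJOR_PHYLA,
                 "PD_WT", "Chao1", "Observed_species", "Shannon",
                 paste0("Unweighted.PCoA", 1:3),
                 paste0("Weighted.PCoA", 1:3))
R2_ROWS <- c("Unweighted UniFrac", "Weighted UniFrac")

#' Compute the per-sample microbiota metrics used in the study reports
#'
#' Produces the 14 per-sample metrics: relative abundances of the four major
#' phyla (from full counts), four rarefied alpha-diversity metrics (mean
#' over draws), and the top three principal coordinates of the unweighted
#' and weighted UniFrac distance matrices. The PCoA is computed once over
#' all samples jointly; condition/time strata are sliced from the shared
#' axes downstream.
#'
#' @param counts Integer matrix, samples x OTUs.
#' @param metadata Sample metadata (see [read_sample_metadata()]).
#' @param tree Rooted `phylo` tree over the OTUs.
#' @param taxonomy Named character vector, OTU id -> phylum.
#' @param depth Rarefaction depth (default 5000).
#' @param draws Rarefaction draws for alpha diversity (default 20).
#' @param seed Master seed.
#' @return Object of class `study_metrics`: `metrics` (data.frame, one row
#'   per sample, one column per metric plus design columns), and `dm`
#'   (list of the two UniFrac [stats::dist] matrices).
#' @export
compute_study_metrics <- function(counts, metadata, tree, taxonomy,
                                  depth = 5000, draws = 20, seed = 1) {
  counts <- validate_count_table(counts)
  metadata <- validate_sample_metadata(metadata)
  if (!setequal(rownames(counts), metadata$sample_id))
    stop("counts and metadata must cover the same samples")
  metadata <- metadata[match(rownames(counts), metadata$sample_id), ]

  comp <- suppressWarnings(relative_abundance(counts))
  phyl <- aggregate_by_phylum(comp, taxonomy)
  phyl_cols <- sapply(MAJOR_PHYLA, function(ph) {
    if (ph %in% colnames(phyl)) phyl[, ph] else rep(0, nrow(phyl))
  })

  alpha <- alpha_diversity(counts, tree = tree, depth = depth, draws = draws,
                           seed = mix_seed(seed, 101))
  dm_u <- unifrac_matrix(counts, tree, "unweighted", depth = depth,
                         seed = mix_seed(seed, 102))
  dm_w <- unifrac_matrix(counts, tree, "weighted", depth = depth,
                         seed = mix_seed(seed, 103))
  pc_u <- pcoa(dm_u, 3)
  pc_w <- pcoa(dm_w, 3)

  m <- data.frame(sample_id = rownames(counts), phyl_cols,
                  row.names = NULL, check.names = FALSE,
                  stringsAsFactors = FALSE)
  m$PD_WT <- alpha$pd
  m$Chao1 <- alpha$chao1
  m$Observed_species <- alpha$observed_species
  m$Shannon <- alpha$shannon
  for (j in 1:3) {
    u <- pc_u$coordinates
    w <- pc_w$coordinates
    m[[paste0("Unweighted.PCoA", j)]] <- if (ncol(u) >= j)
      unname(u[match(m$sample_id, rownames(u)), j]) else NA_real_
    m[[paste0("Weighted.PCoA", j)]] <- if (ncol(w) >= j)
      unname(w[match(m$sample_id, rownames(w)), j]) else NA_real_
  }
  m <- cbind(m, metadata[, c("subject_id", "medium", "time_days", "replicate")])
  structure(list(metrics = m,
                 dm = list(unweighted = dm_u, weighted = dm_w),
                 pcoa = list(unweighted = pc_u, weighted = pc_w)),
            class = "study_metrics")
}

# ICC of one metric across technical replicates within a stratum, grouped by
# subject. Returns NULL when fewer than 2 subjects keep >= 2 replicates.
stratum_icc <- function(values, subjects, n_perm, seed) {
  ok <- !is.na(values)
  values <- values[ok]
  subjects <- subjects[ok]
  tab <- table(subjects)
  keep <- names(tab)[tab >= 2]
  if (length(keep) < 2) return(NULL)
  sel <- subjects %in% keep
  icc_fit(values[sel], subjects[sel], n_perm = n_perm, seed = seed)
}

#' Technical-reproducibility report (ICCs across triplicates)
#'
#' For each collection medium at one time point, computes the ICC across
#' technical replicates (grouped by subject) for the 14 per-sample metrics,
#' with a permutation p-value per ICC, plus the subject-grouping
#' distance-based R-squared for the unweighted and weighted UniFrac
#' matrices restricted to that stratum.
#'
#' @param counts,metadata,tree,taxonomy Study inputs (see
#'   [compute_study_metrics()]).
#' @param time Time point in days (default 0).
#' @param media Media to evaluate; defaults to all media present at `time`.
#' @param depth,draws,seed As in [compute_study_metrics()].
#' @param n_perm Permutations per ICC test (default 999; 0 to skip).
#' @param metrics Optional precomputed [compute_study_metrics()] result.
#' @return Object of class `study_report`: `table` (clamped ICC / R2,
#'   16 rows x media), `raw`, `pvalues`, `n_groups`, `design`.
#' @export
reproducibility_report <- function(counts, metadata, tree, taxonomy,
                                   time = 0, media = NULL,
                                   depth = 5000, draws = 20, n_perm = 999,
                                   seed = 1, metrics = NULL) {
  sm <- metrics %||% compute_study_metrics(counts, metadata, tree, taxonomy,
                                           depth = depth, draws = draws,
                                           seed = seed)
  m <- sm$metrics
  if (is.null(media))
    media <- intersect(MEDIA_LEVELS, unique(as.character(m$medium[m$time_days == time])))
  rows <- c(METRIC_ROWS, R2_ROWS)
  tab <- raw <- pv <- matrix(NA_real_, length(rows), length(media),
                             dimnames = list(rows, media))
  ngr <- matrix(NA_integer_, length(rows), length(media),
                dimnames = list(rows, media))
  for (md in media) {
    sel <- m$medium == md & m$time_days == time
    if (!any(sel)) {
      warning("no samples for medium ", md, " at time ", time)
      next
    }
    for (k in seq_along(METRIC_ROWS)) {
      fit <- stratum_icc(m[[METRIC_ROWS[k]]][sel],
                         as.character(m$subject_id[sel]),
                         n_perm = n_perm,
                         seed = mix_seed(seed, 201, match(md, MEDIA_LEVELS), k))
      if (is.null(fit)) {
        warning("medium ", md, ", metric ", METRIC_ROWS[k],
                ": fewer than 2 subjects with >= 2 replicates; cell left NA")
        next
      }
      tab[k, md] <- fit$icc
      raw[k, md] <- fit$icc_raw
      pv[k, md] <- fit$p_perm
      ngr[k, md] <- fit$n_groups
    }
    ids <- m$sample_id[sel]
    for (kind in c("unweighted", "weighted")) {
      d <- sm$dm[[kind]]
      have <- intersect(ids, attr(d, "Labels"))
      if (length(have) < 3) next
      dmat <- as.matrix(d)[have, have]
      grp <- stats::setNames(as.character(m$subject_id[match(have, m$sample_id)]),
                             have)
      if (length(unique(grp)) < 2) next
      r2 <- dist_r2(stats::as.dist(dmat), grp)
      row <- if (kind == "unweighted") "Unweighted UniFrac" else "Weighted UniFrac"
      tab[row, md] <- raw[row, md] <- r2$r2
      ngr[row, md] <- r2$n_groups
    }
  }
  structure(list(table = tab, raw = raw, pvalues = pv, n_groups = ngr,
                 design = sprintf("reproducibility at time %d", time),
                 time = time, n_perm = n_perm),
            class = "study_report")
}

#' Temporal-stability report (ICCs between time points)
#'
#' For each medium and each later time point, technical replicates are
#' averaged per subject at the later time and at time 0; the stability ICC
#' treats each subject's two averages as its replicate pair. The
#' between-time distance R-squared uses the samples of both time points for
#' the medium, grouped by subject.
#'
#' @inheritParams reproducibility_report
#' @param times Later time points to compare against time 0 (default
#'   `c(3, 7)`).
#' @return A `study_report` whose columns are `medium.d<t>v0`.
#' @export
stability_report <- function(counts, metadata, tree, taxonomy,
                             times = c(3, 7), media = NULL,
                             depth = 5000, draws = 20, n_perm = 0,
                             seed = 1, metrics = NULL) {
  sm <- metrics %||% compute_study_metrics(counts, metadata, tree, taxonomy,
                                           depth = depth, draws = draws,
                                           seed = seed)
  m <- sm$metrics
  if (is.null(media)) {
    media <- intersect(setdiff(MEDIA_LEVELS, "none"),
                       unique(as.character(m$medium[m$time_days %in% times])))
  }
  cols <- as.vector(outer(media, times, function(md, t)
    sprintf("%s.d%dv0", md, t)))
  rows <- c(METRIC_ROWS, R2_ROWS)
  tab <- raw <- pv <- matrix(NA_real_, length(rows), length(cols),
                             dimnames = list(rows, cols))
  subj_avg <- function(values, subjects) {
    out <- tapply(values, subjects, mean, na.rm = TRUE)
    out[!is.nan(out)]
  }
  for (md in media) {
    for (t in times) {
      col <- sprintf("%s.d%dv0", md, t)
      sel_t <- m$medium == md & m$time_days == t
      sel_0 <- m$medium == md & m$time_days == 0
      if (!any(sel_t) || !any(sel_0)) {
        warning("no samples for medium ", md, " at times ", t, "/0")
        next
      }
      for (k in seq_along(METRIC_ROWS)) {
        a_t <- subj_avg(m[[METRIC_ROWS[k]]][sel_t],
                        as.character(m$subject_id[sel_t]))
        a_0 <- subj_avg(m[[METRIC_ROWS[k]]][sel_0],
                        as.character(m$subject_id[sel_0]))
        if (length(intersect(names(a_t), names(a_0))) < 2) next
        fit <- suppressWarnings(
          temporal_icc(a_t, a_0, n_perm = n_perm,
                       seed = mix_seed(seed, 301, match(md, MEDIA_LEVELS), t, k))
        )
        tab[k, col] <- fit$icc
        raw[k, col] <- fit$icc_raw
        pv[k, col] <- fit$p_perm
      }
      ids <- m$sample_id[(sel_t | sel_0)]
      for (kind in c("unweighted", "weighted")) {
        d <- sm$dm[[kind]]
        have <- intersect(ids, attr(d, "Labels"))
        if (length(have) < 3) next
        dmat <- as.matrix(d)[have, have]
        grp <- stats::setNames(
          as.character(m$subject_id[match(have, m$sample_id)]), have)
        if (length(unique(grp)) < 2) next
        r2 <- dist_r2(stats::as.dist(dmat), grp)
        row <- if (kind == "unweighted") "Unweighted UniFrac" else "Weighted UniFrac"
        tab[row, col] <- raw[row, col] <- r2$r2
      }
    }
  }
  structure(list(table = tab, raw = raw, pvalues = pv,
                 design = sprintf("stability, times {%s} vs 0",
                                  paste(times, collapse = ",")),
                 times = times, n_perm = n_perm),
            class = "study_report")
}

#' @export
print.study_report <- function(x, digits = 2, ...) {
  cat("Study report:", x$design, "\n")
  print(round(x$table, digits))
  invisible(x)
}

#' Media composition comparison at time 0
#'
#' Per major phylum: per-subject replicate-averaged relative abundances by
#' medium, the median abundance per medium, and a two-sided paired t-test
#' (no multiplicity correction) of no-media vs each RNAlater-based medium.
#'
#' @inheritParams reproducibility_report
#' @param time Time point (default 0, the only one with no-media samples).
#' @return data.frame with one row per phylum: `median_<medium>` and
#'   `p_<medium>` columns.
#' @export
media_comparison <- function(counts, metadata, taxonomy, time = 0) {
  counts <- validate_count_table(counts)
  metadata <- validate_sample_metadata(metadata)
  metadata <- metadata[match(rownames(counts), metadata$sample_id), ]
  comp <- suppressWarnings(relative_abundance(counts))
  phyl <- aggregate_by_phylum(comp, taxonomy)
  media <- intersect(MEDIA_LEVELS,
                     unique(as.character(metadata$medium[metadata$time_days == time])))
  if (!"none" %in% media) stop("no-media samples required at time ", time)
  out <- data.frame(phylum = MAJOR_PHYLA, stringsAsFactors = FALSE)
  per_subject <- function(ph, md) {
    sel <- metadata$medium == md & metadata$time_days == time
    vals <- if (ph %in% colnames(phyl)) phyl[sel, ph] else rep(0, sum(sel))
    tapply(vals, as.character(metadata$subject_id[sel]), mean)
  }
  for (md in media) {
    out[[paste0("median_", md)]] <- vapply(MAJOR_PHYLA, function(ph)
      stats::median(per_subject(ph, md)), numeric(1))
  }
  for (md in setdiff(media, "none")) {
    out[[paste0("p_", md)]] <- vapply(MAJOR_PHYLA, function(ph) {
      a <- per_subject(ph, "none")
      b <- per_subject(ph, md)
      phylum_media_ttest(a, b)$p
    }, numeric(1))
  }
  out
}

#' Abundance-reproducibility trend for one stratum
#'
#' Computes per-taxon ICCs of relative abundance across technical
#' replicates (grouped by subject) within one (medium, time) stratum,
#' restricted to taxa at or above an abundance floor, and regresses them on
#' log mean relative abundance.
#'
#' @inheritParams reproducibility_report
#' @param medium Stratum medium (default `"rnalater"`).
#' @param time Stratum time (default 0).
#' @param floor Relative-abundance floor (default 0.001 = 0.1%).
#' @param rank `"otu"` (default) or `"phylum"`: taxonomic rank at which the
#'   per-taxon ICCs are computed.
#' @return List with `trend` (an [abundance_icc_trend()] result) and `taxa`
#'   (data.frame of per-taxon abundance and ICC, floor-filtered).
#' @export
abundance_trend_report <- function(counts, metadata, taxonomy = NULL,
                                   medium = "rnalater", time = 0,
                                   floor = 0.001, rank = c("otu", "phylum")) {
  rank <- match.arg(rank)
  counts <- validate_count_table(counts)
  metadata <- validate_sample_metadata(metadata)
  metadata <- metadata[match(rownames(counts), metadata$sample_id), ]
  sel <- metadata$medium == medium & metadata$time_days == time
  if (!any(sel)) stop("no samples in stratum ", medium, "/", time)
  comp <- suppressWarnings(relative_abundance(counts[sel, , drop = FALSE]))
  if (rank == "phylum") {
    if (is.null(taxonomy)) stop("rank = 'phylum' requires a taxonomy map")
    comp <- aggregate_by_phylum(comp, taxonomy)
  }
  subjects <- as.character(metadata$subject_id[sel])
  abund <- colMeans(comp)
  iccs <- vapply(colnames(comp), function(tx) {
    fit <- stratum_icc(comp[, tx], subjects, n_perm = 0, seed = NULL)
    if (is.null(fit)) NA_real_ else fit$icc
  }, numeric(1))
  trend <- abundance_icc_trend(iccs, abund, floor = floor)
  keep <- !is.na(iccs) & abund >= floor
  list(trend = trend,
       taxa = data.frame(taxon = colnames(comp)[keep],
                         abundance = unname(abund[keep]),
                         icc = unname(iccs[keep]),
                         row.names = NULL, stringsAsFactors = FALSE))
}

#' Write a study report to disk
#'
#' Writes the clamped table, raw values and permutation p-values as TSV
#' files plus one combined machine-readable JSON.
#'
#' @param report A `study_report` object.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"report"`).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, prefix = "report") {
  stopifnot(inherits(report, "study_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_mat <- function(mat, name) {
    df <- data.frame(metric = rownames(mat), mat, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, file.path(dir, sprintf("%s_%s.tsv", prefix, name)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_mat(report$table, "icc")
  write_mat(report$raw, "raw")
  write_mat(report$pvalues, "pvalues")
  jsonlite::write_json(
    list(design = report$design, table = report$table, raw = report$raw,
         pvalues = report$pvalues),
    file.path(dir, paste0(prefix, ".json")),
    auto_unbox = TRUE, digits = NA, matrix = "rowmajor"
  )
  invisible(dir)
}
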