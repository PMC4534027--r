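#' Parameters for the synthetic replicated-collection study generator
#'
#' Bundles and validates the generative parameters for [generate_study()].
#' Defaults emulate a 10-subject stool-collection design in which each
#' subject contributes 30 aliquots: 3 no-media aliquots frozen immediately,
#' plus 3 technical replicates at each of days 0, 3 and 7 for three
#' RNAlater-based media (RNAlater alone, + kanamycin, + ciprofloxacin).
#' Expected phylum composition defaults to the major-phyla medians typical of
#' healthy adult stool (Firmicutes 75.1%, Bacteroidetes 14.6%,
#' Actinobacteria 2.1%, Proteobacteria 0.6%; remainder "other").
#'
#' @param n_subjects Number of subjects (default 10).
#' @param n_otus Number of OTUs (default 200, minimum 4).
#' @param depth Sequencing depth per sample: reads drawn from the multinomial
#'   (default 20000).
#' @param sigma_b2 Between-subject variance of per-OTU log abundance
#'   (default 1.0).
#' @param sigma_e2 Within-subject (technical replicate) variance of per-OTU
#'   log abundance (default 0.1). The true per-OTU log-abundance ICC is
#'   `sigma_b2 / (sigma_b2 + sigma_e2)`.
#' @param medium_effects Named list: medium -> named numeric vector of
#'   per-phylum log fold-changes applied to that medium's samples. Default
#'   depletes Bacteroidetes (-1.6) and Proteobacteria (-0.4) in the no-media
#'   condition and leaves the RNAlater media unchanged.
#' @param drift_rates Named numeric: per-day log-abundance drift standard
#'   deviation by medium; the drift realized at day `t` has variance
#'   `drift_rates[medium]^2 * t` and is shared by the replicates of that
#'   (subject, medium, time) aliquot set. Defaults: none 0, rnalater 0.10,
#'   rnalater_kan 0.35, rnalater_cipro 0.35.
#' @param phylum_targets Named numeric: target mean relative abundance per
#'   phylum; must sum to <= 1 (remainder assigned to "other").
#' @param rare_noise_exponent Non-negative exponent `theta` inflating
#'   replicate noise for rare taxa: the per-OTU replicate variance is
#'   `sigma_e2 * (p_max / p_otu)^theta` where `p` is the template abundance.
#'   0 (default) gives abundance-independent replicate noise.
#' @param seed Master seed; all per-sample substreams are derived from it by
#'   counter, so adding subjects does not reshuffle existing ones.
#' @return Object of class `synth_params`.
#' @export
synth_params <- function(n_subjects = 10,
                         n_otus = 200,
                         depth = 20000,
                         sigma_b2 = 1.0,
                         sigma_e2 = 0.1,
                         medium_effects = list(
                           none = c(Bacteroidetes = -1.6, Proteobacteria = -0.4)
                         ),
                         drift_rates = c(none = 0, rnalater = 0.10,
                                         rnalater_kan = 0.35,
                                         rnalater_cipro = 0.35),
                         phylum_targets = c(Firmicutes = 0.751,
                                            Bacteroidetes = 0.146,
                                            Actinobacteria = 0.021,
                                            Proteobacteria = 0.006),
                         rare_noise_exponent = 0,
                         seed = 1) {
  stopifnot(n_subjects >= 1, n_otus >= 4, depth > 0,
            sigma_b2 >= 0, sigma_e2 >= 0, rare_noise_exponent >= 0)
  if (sum(phylum_targets) > 1 + 1e-9)
    stop("phylum_targets must sum to <= 1 (remainder goes to 'other')")
  if (any(phylum_targets < 0)) stop("phylum_targets must be non-negative")
  for (m in names(drift_rates)) {
    if (!m %in% MEDIA_LEVELS) stop("unknown medium in drift_rates: ", m)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_otus = as.integer(n_otus),
                 depth = as.integer(depth),
                 sigma_b2 = sigma_b2, sigma_e2 = sigma_e2,
                 medium_effects = medium_effects,
                 drift_rates = drift_rates,
                 phylum_targets = phylum_targets,
                 rare_noise_exponent = rare_noise_exponent,
                 seed = as.integer(seed)),
            class = "synth_params")
}

#' @export
print.synth_params <- function(x, ...) {
  cat("Synthetic study parameters\n")
  cat(sprintf("  subjects: %d, OTUs: %d, depth: %d reads/sample\n",
              x$n_subjects, x$n_otus, x$depth))
  cat(sprintf("  sigma_b2 = %.3g, sigma_e2 = %.3g (true log-OTU ICC = %.3f)\n",
              x$sigma_b2, x$sigma_e2,
              x$sigma_b2 / (x$sigma_b2 + x$sigma_e2)))
  cat("  drift s.d./day:",
      paste(sprintf("%s=%.2g", names(x$drift_rates), x$drift_rates),
            collapse = ", "), "\n")
  invisible(x)
}

#' Generate a random rooted OTU tree
#'
#' Random rooted binary topology ([ape::rtree()]) with i.i.d. exponential
#' branch lengths of mean 0.1, deterministic given `seed`.
#'
#' @param n_otus Number of leaves (>= 2).
#' @param seed Integer seed.
#' @param labels Leaf labels; defaults to `otu001`, `otu002`, ...
#' @return A rooted `phylo` object.
#' @export
generate_tree <- function(n_otus, seed, labels = NULL) {
  if (n_otus < 2) stop("n_otus must be >= 2")
  if (is.null(labels)) labels <- sprintf("otu%03d", seq_len(n_otus))
  stopifnot(length(labels) == n_otus)
  tree <- with_seed(seed, ape::rtree(n_otus, br = function(n) stats::rexp(n, rate = 10)))
  # rtree labels tips t1..tn in shuffled placement; map ti -> labels[i]
  tree$tip.label <- labels[as.integer(sub("^t", "", tree$tip.label))]
  validate_phylo_tree(tree)
}

# Deterministic OTU template: assign OTUs to phyla and build the baseline
# composition. OTU richness per phylum follows the cube root of its target
# abundance (abundant phyla carry more OTUs, sublinearly); within a phylum,
# abundances follow a Zipf-like power law with exponent 1.5 so that roughly
# half the OTUs fall below 0.1% relative abundance.
otu_template <- function(n_otus, phylum_targets, zipf_exponent = 1.5) {
  other_mass <- 1 - sum(phylum_targets)
  masses <- c(phylum_targets, if (other_mass > 1e-12) c(other = other_mass))
  shares <- masses^(1 / 3)
  shares <- shares / sum(shares)
  k <- length(masses)
  n_k <- rep(0L, k)
  # every phylum with mass gets at least one OTU (largest shares first)
  ord <- order(shares, decreasing = TRUE)
  take <- ord[seq_len(min(k, n_otus))]
  n_k[take] <- 1L
  rem <- n_otus - sum(n_k)
  if (rem > 0) {
    extra <- floor(shares * rem)
    n_k <- n_k + as.integer(extra)
    left <- n_otus - sum(n_k)
    if (left > 0) {
      frac <- shares * rem - extra
      top <- order(frac, decreasing = TRUE)[seq_len(left)]
      n_k[top] <- n_k[top] + 1L
    }
  }
  phylum <- rep(names(masses), times = n_k)
  p0 <- numeric(n_otus)
  idx <- 1L
  for (j in seq_len(k)) {
    if (n_k[j] == 0) next
    w <- seq_len(n_k[j])^(-zipf_exponent)
    p0[idx:(idx + n_k[j] - 1L)] <- masses[j] * w / sum(w)
    idx <- idx + n_k[j]
  }
  p0 <- p0 / sum(p0)
  list(p0 = p0, phylum = phylum)
}

# The replicated-collection design: per subject, 3 no-media aliquots at day 0
# and 3 replicates x days {0,3,7} for each RNAlater-based medium.
study_design <- function(n_subjects) {
  subjects <- sprintf("S%02d", seq_len(n_subjects))
  cells <- rbind(
    data.frame(medium = "none", time_days = 0L, stringsAsFactors = FALSE),
    expand.grid(medium = c("rnalater", "rnalater_kan", "rnalater_cipro"),
                time_days = c(0L, 3L, 7L), stringsAsFactors = FALSE)
  )
  out <- do.call(rbind, lapply(subjects, function(s) {
    do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      data.frame(subject_id = s,
                 medium = cells$medium[i],
                 time_days = cells$time_days[i],
                 replicate = 1:3,
                 stringsAsFactors = FALSE)
    }))
  }))
  out$sample_id <- sprintf("%s_%s_d%d_r%d", out$subject_id, out$medium,
                           out$time_days, out$replicate)
  out[, c("sample_id", "subject_id", "medium", "time_days", "replicate")]
}

#' Simulate a replicated stool-collection study with known ground truth
#'
#' Generates a full study under the reference design (per subject: 3 no-media
#' aliquots at day 0, plus 3 replicates x days 0/3/7 for each of three
#' RNAlater-based media; 30 samples per subject). The hierarchical model on
#' per-OTU log abundance is: template + between-subject effect
#' `N(0, sigma_b2)` + per-phylum medium effect + incubation drift
#' `N(0, drift_rate^2 * days)` (shared by an aliquot set's replicates) +
#' replicate noise `N(0, sigma_e2)`; softmax to a composition; multinomial
#' counts at `depth`. Byte-identical output for identical parameters.
#'
#' @param params A [synth_params()] object.
#' @return Object of class `synth_study`: a list with `counts` (samples x
#'   OTUs integer matrix), `metadata` (data.frame), `tree` (`phylo`),
#'   `taxonomy` (named character), and `truth` (template, realized subject
#'   effects and drifts, per-OTU replicate noise s.d., and the analytic
#'   per-OTU log-abundance ICC).
#' @seealso [synth_params()], [write_study()]
#' @export
generate_study <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  p <- params
  otus <- sprintf("otu%03d", seq_len(p$n_otus))
  tree <- generate_tree(p$n_otus, seed = mix_seed(p$seed, 9001), labels = otus)
  tmpl <- otu_template(p$n_otus, p$phylum_targets)
  taxonomy <- stats::setNames(tmpl$phylum, otus)
  mu0 <- log(tmpl$p0)

  # per-OTU replicate noise s.d., optionally inflated for rare taxa
  noise_var <- p$sigma_e2 *
    (max(tmpl$p0) / tmpl$p0)^p$rare_noise_exponent
  noise_sd <- sqrt(noise_var)

  design <- study_design(p$n_subjects)
  subjects <- unique(design$subject_id)

  subject_eff <- matrix(0, p$n_subjects, p$n_otus,
                        dimnames = list(subjects, otus))
  for (s in seq_along(subjects)) {
    subject_eff[s, ] <- with_seed(mix_seed(p$seed, 1, s),
                                  stats::rnorm(p$n_otus, 0, sqrt(p$sigma_b2)))
  }

  # medium effects expanded to per-OTU vectors
  med_eff <- sapply(MEDIA_LEVELS, function(m) {
    eff <- p$medium_effects[[m]]
    v <- numeric(p$n_otus)
    if (!is.null(eff)) {
      for (ph in names(eff)) v[tmpl$phylum == ph] <- eff[[ph]]
    }
    v
  })

  drifts <- list()
  counts <- matrix(0L, nrow(design), p$n_otus,
                   dimnames = list(design$sample_id, otus))
  for (i in seq_len(nrow(design))) {
    s <- match(design$subject_id[i], subjects)
    m <- match(design$medium[i], MEDIA_LEVELS)
    t_d <- design$time_days[i]
    r <- design$replicate[i]
    drift_key <- sprintf("%s.%s.d%d", subjects[s], MEDIA_LEVELS[m], t_d)
    if (is.null(drifts[[drift_key]])) {
      rate <- p$drift_rates[[MEDIA_LEVELS[m]]] %||% 0
      drifts[[drift_key]] <- if (t_d == 0 || rate == 0) {
        numeric(p$n_otus)
      } else {
        with_seed(mix_seed(p$seed, 2, s, m, t_d),
                  stats::rnorm(p$n_otus, 0, rate * sqrt(t_d)))
      }
    }
    eta <- mu0 + subject_eff[s, ] + med_eff[, m] + drifts[[drift_key]]
    counts[i, ] <- with_seed(mix_seed(p$seed, 3, s, m, t_d, r), {
      eta_i <- eta + stats::rnorm(p$n_otus, 0, noise_sd)
      comp <- exp(eta_i - max(eta_i))
      comp <- comp / sum(comp)
      as.integer(stats::rmultinom(1, p$depth, comp))
    })
  }

  truth <- list(params = p,
                template = tmpl$p0,
                phylum = tmpl$phylum,
                subject_effects = subject_eff,
                drifts = drifts,
                noise_sd = noise_sd,
                true_icc_log_otu = p$sigma_b2 / (p$sigma_b2 + p$sigma_e2))
  structure(list(counts = counts,
                 metadata = validate_sample_metadata(design),
                 tree = tree,
                 taxonomy = taxonomy,
                 truth = truth),
            class = "synth_study")
}

#' @export
print.synth_study <- function(x, ...) {
  cat("Synthetic replicated-collection study\n")
  cat(sprintf("  %d samples x %d OTUs; %d subjects\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$metadata$subject_id))))
  cat(sprintf("  true per-OTU log-abundance ICC: %.3f\n",
              x$truth$true_icc_log_otu))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Writes the count table, metadata, taxonomy (TSV), tree (Newick) and
#' ground truth (JSON) into a directory.
#'
#' @param study A `synth_study` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synth_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_count_table(study$counts, file.path(dir, "counts.tsv"))
  write_sample_metadata(study$metadata, file.path(dir, "metadata.tsv"))
  write_taxonomy(study$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_phylo_tree(study$tree, file.path(dir, "tree.nwk"))
  truth <- study$truth
  truth$params <- unclass(truth$params)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Simulate grouped Gaussian replicates from the one-way random-effects model
#'
#' Draws `value[i,j] = b_i + e[i,j]` with subject effect
#' `b_i ~ N(0, sigma_b2)` and replicate noise `e ~ N(0, sigma_e2)`; the true
#' intraclass correlation is `sigma_b2 / (sigma_b2 + sigma_e2)`. Used for
#' estimator-recovery and permutation-validity checks.
#'
#' @param n_subjects Number of subjects (groups, >= 2).
#' @param k Replicates per subject (>= 2).
#' @param sigma_b2,sigma_e2 Between- and within-subject variances.
#' @param seed Integer seed (optional).
#' @return data.frame with columns `subject` (factor) and `value`; the true
#'   ICC is stored in attribute `true_icc`.
#' @export
generate_gaussian_replicates <- function(n_subjects, k, sigma_b2, sigma_e2,
                                         seed = NULL) {
  stopifnot(n_subjects >= 2, k >= 2, sigma_b2 >= 0, sigma_e2 >= 0)
  out <- with_seed(seed, {
    b <- stats::rnorm(n_subjects, 0, sqrt(sigma_b2))
    data.frame(
      subject = factor(rep(sprintf("S%02d", seq_len(n_subjects)), each = k)),
      value = rep(b, each = k) + stats::rnorm(n_subjects * k, 0, sqrt(sigma_e2))
    )
  })
  attr(out, "true_icc") <- if (sigma_b2 + sigma_e2 == 0) 1 else
    sigma_b2 / (sigma_b2 + sigma_e2)
  out
}
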