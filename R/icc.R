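# One-way random-effects ICC: the reproducibility statistic at the heart of
# the package. The ANOVA (method-of-moments) estimator is used: with G
# groups (subjects) of sizes n_g, N = sum(n_g),
#   MSB = SSB / (G - 1),  MSW = SSW / (N - G),
#   k_eff = (N - sum(n_g^2) / N) / (G - 1),
#   ICC  = (MSB - MSW) / (MSB + (k_eff - 1) * MSW),
# which reduces to sigma_b2 / (sigma_b2 + sigma_e2) with
# sigma_e2_hat = MSW and sigma_b2_hat = max(0, (MSB - MSW) / k_eff).

icc_anova <- function(values, groups) {
  groups <- droplevels(factor(groups))
  g <- nlevels(groups)
  n <- length(values)
  if (g < 2) stop("need at least 2 groups")
  if (any(is.na(values))) stop("values must not contain NA")
  ng <- as.vector(table(groups))
  if (any(ng == 0)) stop("every group needs at least one value")
  if (n - g < 1) stop("no within-group degrees of freedom")
  gi <- as.integer(groups)
  s <- as.vector(rowsum(values, gi))
  grand <- sum(s)
  ssb <- sum(s^2 / ng) - grand^2 / n
  sst <- sum(values^2) - grand^2 / n
  ssw <- max(0, sst - ssb)
  msb <- ssb / (g - 1)
  msw <- ssw / (n - g)
  keff <- (n - sum(ng^2) / n) / (g - 1)
  degenerate <- FALSE
  if (msw <= 0) {
    # no within-group variance: perfectly reproducible by definition
    icc_raw <- 1
    degenerate <- msb <= 0  # all values identical
  } else {
    icc_raw <- (msb - msw) / (msb + (keff - 1) * msw)
  }
  list(icc = clamp01(icc_raw), icc_raw = icc_raw,
       sigma_b2_hat = max(0, (msb - msw) / keff), sigma_e2_hat = msw,
       msb = msb, msw = msw, n_groups = g, k_effective = keff, n = n,
       degenerate = degenerate)
}

# Fast raw-ICC statistic for permutation loops: group sizes fixed, constants
# precomputed by the caller.
icc_stat_fast <- function(values, gi, ng, n, g, keff) {
  s <- as.vector(rowsum(values, gi))
  grand <- sum(s)
  ssb <- sum(s^2 / ng) - grand^2 / n
  sst <- sum(values^2) - grand^2 / n
  msb <- ssb / (g - 1)
  msw <- max(0, sst - ssb) / (n - g)
  if (msw <= 0) return(1)
  (msb - msw) / (msb + (keff - 1) * msw)
}

#' Fit a one-way random-effects ICC model
#'
#' Estimates the intraclass correlation coefficient
#' `ICC = sigma_b2 / (sigma_b2 + sigma_e2)` — the fraction of total variance
#' attributable to between-group (between-subject) differences — from
#' grouped replicate measurements, using the one-way random-effects ANOVA
#' estimator. Unbalanced group sizes are handled through the effective
#' replicate number `k_eff = (N - sum(n_g^2)/N) / (G - 1)`. Optionally
#' attaches a permutation p-value for the null `ICC = 0` (measurements
#' random across replicates): the null distribution is built by shuffling
#' all values across groups with group sizes preserved, and
#' `p = (1 + #\{ICC_perm >= ICC_obs\}) / (n_perm + 1)`.
#'
#' The reported `icc` is clamped to \[0, 1\]; the raw estimator value (which
#' can be negative in small samples) is retained as `icc_raw` and used as
#' the permutation statistic.
#'
#' @param x A formula `value ~ group`, or a numeric vector of values.
#' @param ... Further arguments passed to methods.
#' @return An object of class `icc_fit` with components `icc`, `icc_raw`,
#'   `sigma_b2_hat`, `sigma_e2_hat`, `msb`, `msw`, `n_groups`,
#'   `k_effective`, `n`, `p_perm`, `n_perm`, `degenerate`.
#' @examples
#' d <- generate_gaussian_replicates(10, 3, sigma_b2 = 4, sigma_e2 = 1,
#'                                   seed = 1)
#' fit <- icc_fit(value ~ subject, d, n_perm = 199, seed = 1)
#' fit
#' coef(fit)
#' @export
icc_fit <- function(x, ...) UseMethod("icc_fit")

#' @rdname icc_fit
#' @param data A data.frame containing the formula's variables.
#' @param n_perm Number of permutations for the `ICC = 0` test (0 skips it;
#'   at least 99 otherwise).
#' @param seed Seed for the permutation draw.
#' @export
icc_fit.formula <- function(x, data, n_perm = 0, seed = NULL, ...) {
  mf <- stats::model.frame(x, data)
  if (ncol(mf) != 2) stop("formula must be of the form value ~ group")
  out <- icc_fit.default(mf[[1]], mf[[2]], n_perm = n_perm, seed = seed)
  out$call <- match.call()
  out
}

#' @rdname icc_fit
#' @param groups Group (subject) labels, same length as the values.
#' @export
icc_fit.default <- function(x, groups, n_perm = 0, seed = NULL, ...) {
  values <- as.numeric(x)
  groups <- droplevels(factor(groups))
  fit <- icc_anova(values, groups)
  fit$p_perm <- NA_real_
  fit$n_perm <- 0L
  if (n_perm > 0) {
    if (n_perm < 99) stop("use at least 99 permutations")
    gi <- as.integer(groups)
    ng <- as.vector(table(groups))
    g <- fit$n_groups
    n <- fit$n
    keff <- fit$k_effective
    obs <- fit$icc_raw
    exceed <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(b) {
        icc_stat_fast(sample(values), gi, ng, n, g, keff)
      }, numeric(1)) >= obs)
    })
    fit$p_perm <- (1 + exceed) / (n_perm + 1)
    fit$n_perm <- as.integer(n_perm)
  }
  fit$values <- values
  fit$groups <- groups
  fit$call <- match.call()
  class(fit) <- "icc_fit"
  fit
}

#' @export
print.icc_fit <- function(x, digits = 4, ...) {
  cat("One-way random-effects ICC\n")
  cat(sprintf("  ICC = %.*f", digits, x$icc))
  if (x$icc_raw < 0) cat(sprintf(" (raw estimate %.*f)", digits, x$icc_raw))
  if (x$degenerate) cat(" [degenerate: all values identical]")
  cat("\n")
  cat(sprintf("  sigma_b2 = %.*g, sigma_e2 = %.*g\n",
              digits, x$sigma_b2_hat, digits, x$sigma_e2_hat))
  cat(sprintf("  %d groups, N = %d, k_eff = %.3g\n",
              x$n_groups, x$n, x$k_effective))
  if (!is.na(x$p_perm))
    cat(sprintf("  permutation P(ICC = 0) = %.4g (%d permutations)\n",
                x$p_perm, x$n_perm))
  invisible(x)
}

#' @export
summary.icc_fit <- function(object, ...) {
  gm <- tapply(object$values, object$groups, mean)
  structure(list(fit = object,
                 group_means = gm,
                 grand_mean = mean(object$values)),
            class = "summary.icc_fit")
}

#' @export
print.summary.icc_fit <- function(x, ...) {
  print(x$fit)
  cat("  group means:\n")
  print(round(x$group_means, 4))
  invisible(x)
}

#' @export
coef.icc_fit <- function(object, ...) {
  c(icc = object$icc, sigma_b2 = object$sigma_b2_hat,
    sigma_e2 = object$sigma_e2_hat)
}

#' @export
fitted.icc_fit <- function(object, ...) {
  gm <- tapply(object$values, object$groups, mean)
  as.vector(gm[as.character(object$groups)])
}

#' @export
residuals.icc_fit <- function(object, ...) {
  object$values - fitted(object)
}

#' Simulate replicate datasets from a fitted ICC model
#'
#' Draws new grouped values from the one-way random-effects model at the
#' fitted variance components, preserving the observed group structure.
#'
#' @param object An `icc_fit` object.
#' @param nsim Number of simulated datasets.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A data.frame with one column per simulation (`sim_1`, ...) and
#'   a `groups` attribute-free first column `subject`.
#' @export
simulate.icc_fit <- function(object, nsim = 1, seed = NULL, ...) {
  groups <- object$groups
  g <- nlevels(groups)
  n <- length(groups)
  sims <- with_seed(seed, {
    vapply(seq_len(nsim), function(b) {
      bg <- stats::rnorm(g, 0, sqrt(object$sigma_b2_hat))
      bg[as.integer(groups)] + stats::rnorm(n, 0, sqrt(object$sigma_e2_hat))
    }, numeric(n))
  })
  out <- as.data.frame(sims)
  colnames(out) <- paste0("sim_", seq_len(nsim))
  cbind(data.frame(subject = groups), out)
}

#' Permutation test for a difference in ICC between two conditions
#'
#' Tests whether the reproducibility (ICC) of a measurement differs between
#' two conditions sharing the same subjects. The statistic is
#' `|ICC_a - ICC_b|`; the null distribution swaps, independently per subject
#' with probability 1/2, that subject's full replicate set between the two
#' conditions, and `p = (1 + #\{stat_perm >= stat_obs\}) / (n_perm + 1)`.
#' Subjects present in only one condition are excluded with a warning.
#'
#' @param values_a,values_b Measurement values under conditions a and b.
#' @param groups_a,groups_b Subject labels aligned with the values.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional seed.
#' @return An object of class `htest`.
#' @export
icc_diff_test <- function(values_a, groups_a, values_b, groups_b,
                          n_perm = 999, seed = NULL) {
  groups_a <- as.character(groups_a)
  groups_b <- as.character(groups_b)
  common <- intersect(unique(groups_a), unique(groups_b))
  dropped <- setdiff(union(unique(groups_a), unique(groups_b)), common)
  if (length(dropped) > 0)
    warning("subjects present in one condition only, excluded: ",
            paste(dropped, collapse = ", "))
  if (length(common) < 2) stop("need at least 2 shared subjects")
  sets_a <- split(values_a[groups_a %in% common], groups_a[groups_a %in% common])
  sets_b <- split(values_b[groups_b %in% common], groups_b[groups_b %in% common])
  sets_a <- sets_a[common]
  sets_b <- sets_b[common]
  stat_of <- function(sa, sb) {
    ga <- rep(common, lengths(sa))
    gb <- rep(common, lengths(sb))
    abs(icc_anova(unlist(sa), ga)$icc_raw - icc_anova(unlist(sb), gb)$icc_raw)
  }
  obs <- stat_of(sets_a, sets_b)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(b) {
      flip <- stats::runif(length(common)) < 0.5
      pa <- sets_a
      pb <- sets_b
      pa[flip] <- sets_b[flip]
      pb[flip] <- sets_a[flip]
      stat_of(pa, pb)
    }, numeric(1)) >= obs)
  })
  p <- (1 + exceed) / (n_perm + 1)
  structure(list(statistic = c(`|ICC_a - ICC_b|` = obs),
                 p.value = p,
                 method = "Permutation test for ICC difference (per-subject condition swap)",
                 data.name = sprintf("%d subjects, %d permutations",
                                     length(common), n_perm)),
            class = "htest")
}

#' Temporal-stability ICC between two time points
#'
#' Quantifies how stable a measurement is over delayed freezing: technical
#' replicates are first averaged per subject at each time point, then the
#' ICC is computed over subjects with the pair (average at time t, average
#' at time 0) as each subject's two "replicates" (k = 2). ICC near 1 means
#' the subject ordering and values are preserved over the delay.
#'
#' @param avg_t Named numeric: per-subject replicate-averaged values at the
#'   later time.
#' @param avg_0 Named numeric: same at time 0.
#' @param n_perm,seed Passed to [icc_fit()] for the permutation test.
#' @return An `icc_fit` object.
#' @export
temporal_icc <- function(avg_t, avg_0, n_perm = 0, seed = NULL) {
  if (is.null(names(avg_t)) || is.null(names(avg_0)))
    stop("avg_t and avg_0 must be named by subject")
  common <- intersect(names(avg_t), names(avg_0))
  dropped <- setdiff(union(names(avg_t), names(avg_0)), common)
  if (length(dropped) > 0)
    warning("subjects missing at one time point, excluded: ",
            paste(dropped, collapse = ", "))
  if (length(common) < 2) stop("need at least 2 subjects at both times")
  values <- c(rbind(avg_t[common], avg_0[common]))
  groups <- rep(common, each = 2)
  icc_fit(values, groups, n_perm = n_perm, seed = seed)
}

#' Paired t-test for phylum abundance between collection conditions
#'
#' Two-sided paired t-test (no multiple-testing correction) comparing
#' per-subject replicate-averaged phylum relative abundances between two
#' collection conditions, e.g. no-media vs RNAlater.
#'
#' @param x_no_media Named numeric: per-subject values under the reference
#'   condition.
#' @param x_media Named numeric: per-subject values under the comparison
#'   condition (same subjects).
#' @return A list with `t`, `p`, `df`, `mean_difference`, `n`, `degenerate`.
#'   When the paired differences have zero variance, `p` is 1 when the mean
#'   difference is 0 and the result is flagged degenerate otherwise.
#' @export
phylum_media_ttest <- function(x_no_media, x_media) {
  if (!is.null(names(x_no_media)) && !is.null(names(x_media))) {
    common <- intersect(names(x_no_media), names(x_media))
    x_no_media <- x_no_media[common]
    x_media <- x_media[common]
  }
  n <- length(x_no_media)
  if (n < 3) stop("need at least 3 paired subjects")
  d <- x_media - x_no_media
  if (stats::sd(d) <= 1e-12 * max(1, abs(mean(d)))) {
    if (mean(d) == 0) {
      return(list(t = 0, p = 1, df = n - 1, mean_difference = 0, n = n,
                  degenerate = TRUE))
    }
    return(list(t = Inf * sign(mean(d)), p = NA_real_, df = n - 1,
                mean_difference = mean(d), n = n, degenerate = TRUE))
  }
  tt <- stats::t.test(x_media, x_no_media, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_difference = unname(tt$estimate),
       n = n, degenerate = FALSE)
}

#' Abundance-reproducibility trend regression
#'
#' Ordinary least-squares regression of per-taxon ICC on the natural log of
#' mean relative abundance, restricted to taxa at or above an abundance
#' floor (default 0.1%). A positive slope means abundant taxa are measured
#' more reproducibly than rare ones.
#'
#' @param icc Named numeric: per-taxon ICC.
#' @param abundance Named numeric: per-taxon mean relative abundance, same
#'   taxa as `icc`.
#' @param floor Minimum relative abundance for inclusion (default 0.001,
#'   i.e. 0.1%; inclusive).
#' @return Object of class `icc_trend`: `slope`, `intercept`, `p_value`
#'   (two-sided, for the slope), `n_taxa`, and the underlying `lm` fit.
#' @export
abundance_icc_trend <- function(icc, abundance, floor = 0.001) {
  if (!is.null(names(icc)) && !is.null(names(abundance))) {
    common <- intersect(names(icc), names(abundance))
    icc <- icc[common]
    abundance <- abundance[common]
  }
  if (length(icc) != length(abundance))
    stop("icc and abundance must cover the same taxa")
  keep <- !is.na(icc) & !is.na(abundance) & abundance >= floor
  if (sum(keep) < 3)
    stop("fewer than 3 taxa at or above the abundance floor")
  df <- data.frame(icc = icc[keep], log_abund = log(abundance[keep]))
  fit <- stats::lm(icc ~ log_abund, data = df)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 p_value = sm$coefficients[2, 4],
                 n_taxa = sum(keep),
                 model = fit),
            class = "icc_trend")
}

#' @export
print.icc_trend <- function(x, ...) {
  cat("ICC vs log relative abundance trend\n")
  cat(sprintf("  slope = %.4f per log unit (P = %.3g), intercept = %.4f, %d taxa\n",
              x$slope, x$p_value, x$intercept, x$n_taxa))
  invisible(x)
}
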