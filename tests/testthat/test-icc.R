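test_that("the one-way ICC estimator matches hand ANOVA computations", {
  # zero within-group variance
  expect_equal(icc_fit(c(1, 1, 5, 5), c("a", "a", "b", "b"))$icc, 1.0)
  # groups (1,2) and (3,4): MSB = 4, MSW = 0.5, icc = 3.5/4.5
  fit <- icc_fit(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(fit$msb, 4)
  expect_equal(fit$msw, 0.5)
  expect_equal(fit$icc_raw, 3.5 / 4.5, tolerance = 1e-12)
  expect_equal(fit$sigma_e2_hat, 0.5)
  expect_equal(fit$sigma_b2_hat, (4 - 0.5) / 2)
  # all values identical: defined as 1, flagged degenerate
  dg <- icc_fit(rep(2, 6), rep(c("a", "b", "c"), each = 2))
  expect_equal(dg$icc, 1.0)
  expect_true(dg$degenerate)
  expect_error(icc_fit(1:3, c("a", "a", "a")), "2 groups")
})

test_that("the estimator matches an independent brute-force ANOVA on random data", {
  set.seed(22)
  for (i in 1:20) {
    g <- sample(3:6, 1)
    sizes <- sample(2:4, g, replace = TRUE)
    groups <- rep(letters[1:g], sizes)
    values <- rnorm(length(groups), rep(rnorm(g, sd = 2), sizes))
    fit <- icc_fit(values, groups)
    orc <- oracle_icc(values, groups)
    expect_equal(fit$msb, orc$msb, tolerance = 1e-12)
    expect_equal(fit$msw, orc$msw, tolerance = 1e-12)
    expect_equal(fit$icc_raw, orc$icc, tolerance = 1e-12)
    # and the mean squares agree with stats::aov
    av <- summary(stats::aov(values ~ factor(groups)))[[1]]
    expect_equal(fit$msb, av[["Mean Sq"]][1], tolerance = 1e-10)
    expect_equal(fit$msw, av[["Mean Sq"]][2], tolerance = 1e-10)
  }
})

test_that("the ICC is invariant to location and positive scale changes", {
  set.seed(23)
  values <- rnorm(18, rep(rnorm(6, sd = 2), each = 3))
  groups <- rep(letters[1:6], each = 3)
  base <- icc_fit(values, groups)$icc_raw
  expect_equal(icc_fit(values + 100, groups)$icc_raw, base, tolerance = 1e-9)
  expect_equal(icc_fit(values * 7.5, groups)$icc_raw, base, tolerance = 1e-9)
})

test_that("formula and default interfaces agree and methods are coherent", {
  d <- generate_gaussian_replicates(8, 3, 4, 1, seed = 24)
  f1 <- icc_fit(value ~ subject, d)
  f2 <- icc_fit(d$value, d$subject)
  expect_equal(f1$icc, f2$icc)
  expect_named(coef(f1), c("icc", "sigma_b2", "sigma_e2"))
  expect_equal(length(residuals(f1)), nrow(d))
  expect_equal(fitted(f1) + residuals(f1), d$value)
  sims <- simulate(f1, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(nrow(d), 4))
  expect_output(print(f1), "ICC")
  expect_output(print(summary(f1)), "group means")
})

test_that("permutation p-values hit the attainable minimum for separated groups", {
  values <- c(1, 1.01, 1.02, 10, 10.01, 10.02, 20, 20.01, 20.02)
  groups <- rep(c("a", "b", "c"), each = 3)
  fit <- icc_fit(values, groups, n_perm = 999, seed = 1)
  expect_lt(fit$p_perm, 0.02)
  expect_gte(fit$p_perm, 1 / 1000)
  expect_error(icc_fit(values, groups, n_perm = 10), "99")
})

test_that("the ICC difference test behaves at the extremes", {
  d <- generate_gaussian_replicates(10, 3, 4, 1, seed = 25)
  same <- icc_diff_test(d$value, d$subject, d$value, d$subject,
                        n_perm = 199, seed = 1)
  expect_equal(unname(same$statistic), 0)
  expect_gt(same$p.value, 0.5)
  # perfectly reproducible vs pure noise: detectable with 10 subjects
  a <- generate_gaussian_replicates(10, 3, 4, 0.0001, seed = 26)
  b <- generate_gaussian_replicates(10, 3, 0.0001, 4, seed = 27)
  diff <- icc_diff_test(a$value, a$subject, b$value, b$subject,
                        n_perm = 199, seed = 1)
  expect_lt(diff$p.value, 0.05)
  # unmatched subjects are dropped with a warning
  expect_warning(
    icc_diff_test(a$value, a$subject,
                  b$value[1:27], b$subject[1:27], n_perm = 99, seed = 1),
    "excluded"
  )
})

test_that("the ICC difference test holds its size under a shared null", {
  rejections <- vapply(1:100, function(s) {
    a <- generate_gaussian_replicates(8, 3, 1, 1, seed = 1000 + 2 * s)
    b <- generate_gaussian_replicates(8, 3, 1, 1, seed = 1001 + 2 * s)
    icc_diff_test(a$value, a$subject, b$value, b$subject,
                  n_perm = 99, seed = s)$p.value <= 0.05
  }, logical(1))
  expect_lt(mean(rejections), 0.12)
})

test_that("temporal ICC treats per-subject time averages as replicate pairs", {
  # identical values at both times, distinct between subjects
  expect_equal(temporal_icc(c(S1 = 1, S2 = 3), c(S1 = 1, S2 = 3))$icc, 1.0)
  # no subject signal between times: ICC near zero on average
  m <- mean(vapply(1:200, function(s) {
    set.seed(s)
    temporal_icc(setNames(rnorm(10), paste0("S", 1:10)),
                 setNames(rnorm(10), paste0("S", 1:10)))$icc_raw
  }, numeric(1)))
  expect_lt(abs(m), 0.08)
  expect_warning(temporal_icc(c(S1 = 1, S2 = 3, S3 = 2), c(S1 = 1, S2 = 3)),
                 "excluded")
})

test_that("the paired phylum t-test matches a hand computation", {
  a <- c(S1 = 0.1, S2 = 0.2, S3 = 0.15)
  b <- c(S1 = 0.3, S2 = 0.5, S3 = 0.4)
  res <- phylum_media_ttest(a, b)
  d <- b - a  # (0.2, 0.3, 0.25)
  t_hand <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t_hand), df = 2), tolerance = 1e-12)
  ident <- phylum_media_ttest(a, a)
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  expect_true(ident$degenerate)
  shifted <- phylum_media_ttest(a, a + 1)
  expect_true(shifted$degenerate)
  expect_error(phylum_media_ttest(a[1:2], b[1:2]), "3 paired")
})

test_that("the abundance-ICC trend regression recovers noiseless signals", {
  abund <- setNames(10^seq(-4, -0.5, length.out = 12), paste0("t", 1:12))
  icc <- 0.2 + 0.05 * log(abund)
  tr <- suppressWarnings(abundance_icc_trend(icc, abund, floor = 0))
  expect_equal(tr$slope, 0.05, tolerance = 1e-9)
  expect_equal(tr$intercept, 0.2, tolerance = 1e-9)
  expect_lt(tr$p_value, 1e-9)
  expect_equal(tr$n_taxa, 12)
})

test_that("the abundance floor excludes taxa at 0.09% and keeps 0.11%", {
  abund <- c(a = 0.0009, b = 0.0011, c = 0.02, d = 0.3, e = 0.05)
  icc <- c(a = 0.5, b = 0.6, c = 0.7, d = 0.9, e = 0.8)
  tr <- abundance_icc_trend(icc, abund)
  expect_equal(tr$n_taxa, 4)
  expect_error(abundance_icc_trend(icc[1:3], abund[1:3], floor = 0.5),
               "fewer than 3")
})

test_that("the trend slope is centred on zero when ICC ignores abundance", {
  set.seed(28)
  slopes <- vapply(1:100, function(s) {
    abund <- setNames(10^runif(20, -4, -1), paste0("t", 1:20))
    icc <- runif(20, 0.5, 1)
    abundance_icc_trend(icc, abund, floor = 0)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes)), 0.01)
})
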