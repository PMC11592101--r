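test_that("probe MAD matches hand computation and is symmetric", {
  expect_equal(probe_mad(c(0.1, 0.2, 0.3), c(0.2, 0.1, 0.5)),
               (0.1 + 0.1 + 0.2) / 3)
  expect_equal(probe_mad(c(0.4, 0.5), c(0.4, 0.5)), 0)
  set.seed(7)
  a <- runif(20); b <- runif(20)
  expect_identical(probe_mad(a, b), probe_mad(b, a))
  expect_error(probe_mad(numeric(0), numeric(0)), ">= 1")
})

test_that("worst-case aggregation reproduces the published per-probe summaries", {
  # per-cohort values as printed for the top hyperstable probes
  expect_equal(aggregate_mmad(c(0.00941, 0.00841, 0.00689)), 0.00941)
  expect_equal(aggregate_mmad(c(0.00825, 0.00916, 0.00942)), 0.00942)
  expect_equal(aggregate_mmad(0.5), 0.5)
  expect_error(aggregate_mmad(numeric(0)))

  expect_equal(aggregate_min_icc(c(0.917, 0.923, 0.958)), 0.917)
  expect_equal(aggregate_min_icc(0.3), 0.3)
  expect_true(is.na(aggregate_min_icc(c(0.9, NA, 0.8))))

  expect_equal(aggregate_min_p(c(0.270, 0.208, 0.0701)), 0.0701)
  expect_equal(aggregate_min_p(c(0.214, 0.129, 0.260)), 0.129)
})

test_that("paired t p-value matches stats::t.test and handles degenerate input", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    a <- runif(n); b <- a + rnorm(n, 0.02, 0.05)
    b <- pmin(pmax(b, 0), 1)
    expect_equal(paired_t_p(a, b),
                 stats::t.test(b, a, paired = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # constant nonzero shift: t -> infinity
  a <- seq(0.1, 0.55, by = 0.05)
  expect_lt(paired_t_p(a, a + 0.1), 1e-6)
  # exactly antisymmetric differences: t = 0, p = 1
  d <- c(0.02, -0.02, 0.04, -0.04)
  expect_equal(paired_t_p(rep(0.5, 4), 0.5 + d), 1)
  # exactly zero-variance differences are undefined
  expect_true(is.na(paired_t_p(a, a)))
})

test_that("paired Pearson correlation matches the covariance formula", {
  t1 <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(pearson_paired(t1, 2 * t1), 1)
  expect_lt(pearson_paired(t1, rev(t1)), 0)
  set.seed(5)
  a <- runif(30); b <- runif(30)
  direct <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_paired(a, b), direct, tolerance = 1e-12)
  expect_true(is.na(pearson_paired(rep(0.5, 5), runif(5))))
})

test_that("pooled SD and MAD/SD ratio behave as documented", {
  expect_equal(probe_sd(c(0, 1)), sqrt(0.5))
  expect_equal(probe_sd(rep(0.3, 10)), 0)
  set.seed(9)
  x <- runif(50)
  expect_equal(probe_sd(x), sqrt(sum((x - mean(x))^2) / 49), tolerance = 1e-12)
  expect_error(probe_sd(0.5), ">= 2")

  # published ratio: printed inputs give 0.3147, printed as 0.314
  expect_lt(abs(mad_sd_ratio(0.00941, 0.0299) - 0.314), 0.002)
  expect_equal(mad_sd_ratio(0.02, 0.02), 1)
  expect_equal(mad_sd_ratio(0, 0.1), 0)
  expect_true(is.na(mad_sd_ratio(0.01, 0)))
})

test_that("cross-cohort metric correlation is a guarded Pearson r", {
  x <- runif(100)
  expect_equal(metric_correlation(x, x), 1)
  set.seed(13)
  a <- runif(10000); b <- runif(10000)
  expect_lt(abs(metric_correlation(a, b)), 0.05)
  expect_error(metric_correlation(1:2 / 10, 1:2 / 10), ">= 3")
  a[1:9998] <- NA
  expect_error(metric_correlation(a, b), ">= 3")
})

test_that("stability table: noiseless cohorts give MAD 0 and ICC 1", {
  set.seed(31)
  t1 <- matrix(runif(200 * 8), 200, 8,
               dimnames = list(sprintf("cg%03d", 1:200), NULL))
  co <- cohort_from_matrices(t1, t1)
  tab <- compute_stability_table(list(co))
  expect_true(all(tab$mad_c1 == 0))
  expect_equal(tab$icc_c1, rep(1, 200))
  expect_true(all(is.na(tab$t_p_c1)))     # zero-variance differences
  expect_equal(tab$mmad, tab$mad_c1)      # single cohort: aggregate identity
  expect_equal(tab$min_icc, tab$icc_c1)
})

test_that("stability table aggregates are the per-cohort extremes", {
  set.seed(32)
  make_cohort <- function(cid, noise) {
    t1 <- matrix(runif(50 * 12, 0.2, 0.8), 50, 12,
                 dimnames = list(sprintf("cg%03d", 1:50), NULL))
    t2 <- pmin(pmax(t1 + rnorm(length(t1), 0, noise), 0), 1)
    cohort_from_matrices(t1, t2, cid)
  }
  cohorts <- list(make_cohort("a", 0.02), make_cohort("b", 0.05),
                  make_cohort("c", 0.1))
  tab <- compute_stability_table(cohorts)
  mads <- as.matrix(tab[, c("mad_a", "mad_b", "mad_c")])
  iccs <- as.matrix(tab[, c("icc_a", "icc_b", "icc_c")])
  expect_equal(tab$mmad, apply(mads, 1, max))
  expect_equal(tab$min_icc, apply(iccs, 1, min))
  expect_true(all(tab$mmad >= mads))
  expect_true(all(tab$min_icc <= iccs))
  expect_equal(tab$mean_sd, rowMeans(as.matrix(tab[, c("sd_a", "sd_b", "sd_c")])))
  expect_equal(tab$mad_sd_ratio, tab$mmad / tab$mean_sd)
})

test_that("technical replicates are averaged per subject and timepoint", {
  v <- matrix(c(0.2, 0.4,   # s1_t1
                0.3, 0.5,   # s1_t2 replicate 1
                0.5, 0.7,   # s1_t2 replicate 2
                0.6, 0.8,   # s2_t1
                0.6, 0.9),  # s2_t2
              nrow = 2)
  dimnames(v) <- list(c("cgA", "cgB"),
                      c("a1", "a2", "a3", "b1", "b2"))
  design <- study_design("c1", data.frame(
    subject_id = c("s1", "s1", "s1", "s2", "s2"),
    timepoint = c(1L, 2L, 2L, 1L, 2L),
    sample_id = c("a1", "a2", "a3", "b1", "b2")))
  pm <- paired_matrices(beta_matrix(v), design, replicates = "average")
  expect_equal(pm$t2[, "s1"], c(cgA = 0.4, cgB = 0.6))  # mean of replicates
  tab <- compute_stability_table(list(list(beta = beta_matrix(v),
                                           design = design)))
  expect_equal(tab$mad_c1, c(mean(abs(c(0.4 - 0.2, 0.6 - 0.6))),
                             mean(abs(c(0.6 - 0.4, 0.9 - 0.8)))))
  pm_drop <- paired_matrices(beta_matrix(v), design, replicates = "drop")
  expect_equal(pm_drop$t2[, "s1"], c(cgA = 0.3, cgB = 0.5))  # first sample
})

test_that("missing pairs are removed per probe and sparse probes get NA ICC", {
  set.seed(33)
  t1 <- matrix(runif(4 * 10), 4, 10,
               dimnames = list(paste0("cg", 1:4), NULL))
  t2 <- pmin(t1 + 0.01, 1)
  t1[2, 1:3] <- NA          # probe 2: 7 complete pairs
  t2[3, 1:8] <- NA          # probe 3: 2 complete pairs -> ICC undefined
  co <- cohort_from_matrices(t1, t2)
  tab <- compute_stability_table(list(co))
  expect_false(is.na(tab$icc_c1[2]))
  expect_true(is.na(tab$icc_c1[3]))
  expect_true(is.na(tab$min_icc[3]))      # sentinel propagates
  expect_equal(tab$mad_c1[3], 0.01, tolerance = 1e-12)  # MAD needs only 1 pair
})
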