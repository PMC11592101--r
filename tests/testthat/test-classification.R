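test_that("genetic influence union obeys inclusion-exclusion on published set sizes", {
  # constructed sets with the published cardinalities:
  # 82,491 SNP probes; per-cohort gap calls 20,171 / 40,222 / 14,484 with a
  # 54,330-probe union, 12,151 of which carry a SNP flag
  n_all <- 450079
  ids <- sprintf("p%06d", seq_len(n_all))
  snp <- ids[1:82491]
  gap_union <- c(ids[70341:82491], ids[82492:124670])  # 12151 + 42179
  stopifnot(length(gap_union) == 54330)
  gap1 <- gap_union[1:20171]
  gap2 <- gap_union[1:40222]
  gap3 <- gap_union[39847:54330]
  stopifnot(length(gap3) == 14484)
  ann <- data.frame(probe_id = ids, snp_flag = ids %in% snp)
  gap_calls <- lapply(list(children = gap1, elderly = gap2, middle = gap3),
                      function(g) data.frame(probe_id = g, has_gap = TRUE))
  res <- genetic_influence(ann, gap_calls)
  expect_equal(res$summary$n_snp, 82491)
  expect_equal(unname(res$summary$n_gap_per_cohort),
               c(20171L, 40222L, 14484L))
  expect_equal(res$summary$n_gap_union, 54330)
  expect_equal(res$summary$n_overlap, 12151)
  expect_equal(res$summary$n_union, 124670)
  expect_equal(res$summary$n_union,
               res$summary$n_snp + res$summary$n_gap_union -
                 res$summary$n_overlap)
  expect_equal(sum(res$genetic), 124670)
})

test_that("genetic influence uses the any-cohort rule and validates probes", {
  ann <- data.frame(probe_id = c("a", "b", "c"),
                    snp_flag = c(FALSE, FALSE, FALSE))
  gc1 <- data.frame(probe_id = c("a", "b", "c"),
                    has_gap = c(FALSE, FALSE, FALSE))
  gc2 <- data.frame(probe_id = c("a", "b", "c"),
                    has_gap = c(FALSE, TRUE, FALSE))
  res <- genetic_influence(ann, list(gc1, gc2))
  expect_equal(unname(res$genetic), c(FALSE, TRUE, FALSE))

  res0 <- genetic_influence(ann, list(gc1))
  expect_equal(sum(res0$genetic), 0L)

  gc_bad <- data.frame(probe_id = "zz", has_gap = TRUE)
  expect_error(genetic_influence(ann, list(gc_bad)), "absent from annotation")
})

test_that("inclusion-exclusion holds on random SNP/gap assignments", {
  set.seed(301)
  for (i in 1:20) {
    n <- sample(50:500, 1)
    ids <- sprintf("p%04d", seq_len(n))
    ann <- data.frame(probe_id = ids, snp_flag = runif(n) < 0.3)
    gcs <- lapply(1:3, function(j)
      data.frame(probe_id = ids, has_gap = runif(n) < 0.2))
    res <- genetic_influence(ann, gcs)
    expect_equal(res$summary$n_union,
                 res$summary$n_snp + res$summary$n_gap_union -
                   res$summary$n_overlap)
    expect_equal(sum(res$genetic), res$summary$n_union)
  }
})

test_that("percentile thresholds use linear-interpolation quantiles with overrides", {
  tab <- data.frame(probe_id = sprintf("p%03d", 1:100),
                    mmad = 0.001 * (1:100),
                    min_icc = seq(0, 0.99, length.out = 100),
                    mean_sd = rep(0.05, 100))
  cuts <- percentile_thresholds(tab, classification_config())
  # type-7 quantile: h = 99 * 0.05 + 1 = 5.95
  expect_equal(cuts$mmad_cut, 0.005 + 0.95 * 0.001)
  expect_equal(cuts$icc_cut, unname(quantile(tab$min_icc, 0.95, type = 7)))

  cuts <- percentile_thresholds(
    tab, classification_config(fixed_mmad_cut = 0.01, fixed_icc_cut = 0.74))
  expect_equal(cuts$mmad_cut, 0.01)
  expect_equal(cuts$icc_cut, 0.74)

  tab$mmad <- 0.02
  cuts <- percentile_thresholds(tab, classification_config())
  expect_equal(cuts$mmad_cut, 0.02)  # constant vector

  tab$min_icc <- NA_real_
  expect_error(percentile_thresholds(tab, classification_config()),
               "undefined")
})

test_that("classification applies strict cuts, quadrants and sentinel rules", {
  tab <- data.frame(
    probe_id = paste0("p", 1:6),
    mmad = c(0.005, 0.005, 0.02, 0.02, 0.01, 0.004),
    min_icc = c(0.9, 0.5, 0.9, 0.5, 0.74, NA),
    mean_sd = c(0.03, 0.02, 0.15, 0.12, 0.05, 0.01))
  genetic <- c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)
  cuts <- list(mmad_cut = 0.01, icc_cut = 0.74)
  cls <- classify_probes(tab, genetic, cuts)
  expect_equal(cls$quadrant,
               c("lowMMAD_highICC", "lowMMAD_lowICC", "highMMAD_highICC",
                 "highMMAD_lowICC", "highMMAD_lowICC", NA))
  expect_equal(cls$hyperstable, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  # probe exactly at a cut is not hyperstable and lands in the "high"/"low" side
  expect_false(cls$hyperstable[5])
  expect_equal(cls$invariant, tab$mean_sd < 0.1)

  # genetic exclusion is downstream of the stability criterion
  cls2 <- classify_probes(tab, c(TRUE, rep(FALSE, 5)), cuts)
  expect_true(cls2$hyperstable[1])
  expect_false(cls2$hyperstable_nongenetic[1])
})

test_that("hyperstable set equals the independent intersection of criteria", {
  set.seed(302)
  n <- 500
  tab <- data.frame(probe_id = sprintf("p%04d", 1:n),
                    mmad = rlnorm(n, log(0.02), 0.5),
                    min_icc = runif(n, -0.2, 1),
                    mean_sd = runif(n, 0.01, 0.2))
  genetic <- runif(n) < 0.25
  cuts <- percentile_thresholds(tab, classification_config())
  cls <- classify_probes(tab, genetic, cuts)
  expect_equal(sum(cls$hyperstable),
               length(intersect(which(tab$mmad < cuts$mmad_cut),
                                which(tab$min_icc > cuts$icc_cut))))
  expect_true(all(cls$quadrant[cls$hyperstable] == "lowMMAD_highICC"))
  expect_true(all(cls$hyperstable[cls$hyperstable_nongenetic]))
  expect_false(any(cls$genetic & cls$hyperstable_nongenetic))
})

test_that("high-ICC nongenetic probes land in the low-MMAD/high-ICC quadrant", {
  spec <- synthetic_spec(n_cohorts = 2, n_subjects = 50, n_probes = 600,
                         class_fractions = c(invariant = 0.3, dynamic = 0.4,
                                             stable_nongenetic = 0.3,
                                             genetic = 0),
                         seed = 303)
  cohorts <- lapply(1:2, function(i) {
    co <- generate_cohort(spec, i)
    list(beta = co$beta, design = co$design)
  })
  truth <- generate_cohort(spec, 1)$truth
  tab <- compute_stability_table(cohorts)
  cls <- classify_probes(tab, setNames(rep(FALSE, nrow(tab)), tab$probe_id),
                         list(mmad_cut = 0.01, icc_cut = 0.74))
  stable <- truth$probe_id[truth$class == "stable_nongenetic"]
  frac <- mean(cls$quadrant[match(stable, cls$probe_id)] == "lowMMAD_highICC")
  expect_gte(frac, 0.9)
})
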