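# Independent oracles, written from the textbook definitions and kept free
# of any package internals.

# Two-way ANOVA mean squares by explicit sums over the n x 2 table.
anova_ms_bruteforce <- function(t1, t2) {
  n <- length(t1)
  x <- cbind(t1, t2)
  grand <- mean(x)
  ssr <- 0
  for (i in seq_len(n)) ssr <- ssr + 2 * (mean(x[i, ]) - grand)^2
  ssc <- 0
  for (j in 1:2) ssc <- ssc + n * (mean(x[, j]) - grand)^2
  sst <- 0
  for (i in seq_len(n)) for (j in 1:2) sst <- sst + (x[i, j] - grand)^2
  sse <- sst - ssr - ssc
  list(msr = unname(ssr) / (n - 1), msc = unname(ssc) / 1,
       mse = unname(sse) / ((n - 1) * 1))
}

# Absolute-agreement single-measure ICC from brute-force mean squares.
icc_a1_oracle <- function(t1, t2) {
  n <- length(t1)
  k <- 2
  ms <- anova_ms_bruteforce(t1, t2)
  (ms$msr - ms$mse) /
    (ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse))
}

# Same mean squares via stats::aov, as a second, independent route.
anova_ms_aov <- function(t1, t2) {
  n <- length(t1)
  df <- data.frame(y = c(t1, t2),
                   subject = factor(rep(seq_len(n), 2)),
                   time = factor(rep(1:2, each = n)))
  tab <- summary(stats::aov(y ~ subject + time, data = df))[[1]]
  list(msr = tab["subject", "Mean Sq"],
       msc = tab["time", "Mean Sq"],
       mse = tab["Residuals", "Mean Sq"])
}

# Small helper: a beta_matrix with random values under a fixed seed.
random_beta <- function(n_probes, n_samples, seed = 1, detp = FALSE) {
  set.seed(seed)
  v <- matrix(runif(n_probes * n_samples), n_probes, n_samples,
              dimnames = list(sprintf("cg%06d", seq_len(n_probes)),
                              sprintf("s%03d", seq_len(n_samples))))
  d <- if (detp) matrix(runif(length(v), 0, 0.005), nrow(v), ncol(v),
                        dimnames = dimnames(v)) else NULL
  beta_matrix(v, d)
}

# Cohort bundle (beta + design) for a given probes x subjects pair of
# timepoint matrices, bypassing the generator.
cohort_from_matrices <- function(t1, t2, cohort_id = "c1") {
  n <- ncol(t1)
  subjects <- sprintf("s%03d", seq_len(n))
  v <- cbind(t1, t2)
  colnames(v) <- c(paste0(subjects, "_t1"), paste0(subjects, "_t2"))
  design <- study_design(cohort_id, data.frame(
    subject_id = rep(subjects, 2),
    timepoint = rep(c(1L, 2L), each = n),
    sample_id = colnames(v), stringsAsFactors = FALSE))
  list(beta = beta_matrix(v), design = design)
}
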