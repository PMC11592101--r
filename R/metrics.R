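#' Per-probe mean absolute difference between timepoints
#'
#' The MAD of a probe in one cohort is the mean over subjects of the
#' absolute beta-value change |t2 - t1|. It measures absolute instability on
#' the beta scale and is symmetric in the two timepoints.
#'
#' @param t1,t2 numeric vectors of beta values, one entry per subject,
#'   pairwise complete (drop incomplete pairs before calling).
#' @return Mean absolute difference (beta fraction).
#' @export
probe_mad <- function(t1, t2) {
  .check_paired(t1, t2, min_n = 1L)
  mean(abs(t2 - t1))
}

#' Worst-case aggregation of per-cohort MADs
#'
#' The maximum MAD (MMAD) across cohorts summarises a probe by its poorest
#' absolute stability. Aggregation is done on unrounded values.
#'
#' @param mads numeric vector of per-cohort MAD values.
#' @return Maximum of the inputs.
#' @export
aggregate_mmad <- function(mads) {
  if (!length(mads)) stop("no MAD values to aggregate", call. = FALSE)
  max(mads)
}

#' Two-way absolute-agreement single-measure intraclass correlation
#'
#' ICC(A,1) for n subjects measured at k = 2 timepoints, from the two-way
#' ANOVA mean squares: MSR (between subjects), MSC (between timepoints) and
#' MSE (residual),
#' \deqn{ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE)).}
#' Unlike the consistency form, it penalises systematic shifts between
#' timepoints. The 95% confidence interval is the McGraw & Wong F-based
#' interval with Satterthwaite denominator degrees of freedom.
#'
#' @param t1,t2 numeric vectors of beta values per subject (pairwise
#'   complete). At least 2 subjects for the point estimate, 3 for a finite
#'   CI.
#' @param conf_level confidence level for the interval.
#' @return List with `icc`, `ci_low`, `ci_high`. When the table has zero
#'   total variance the coefficient is undefined and all three are `NA`.
#' @export
icc_a1 <- function(t1, t2, conf_level = 0.95) {
  .check_paired(t1, t2, min_n = 2L)
  n <- length(t1)
  ms <- .icc_mean_squares(t1, t2)
  if (ms$sst <= .zero_var_tol(c(t1, t2)))
    return(list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
  k <- 2
  icc <- (ms$msr - ms$mse) /
    (ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse))
  ci <- .icc_a1_ci(icc, ms$msr, ms$msc, ms$mse, n, k, conf_level)
  list(icc = icc, ci_low = ci[1], ci_high = ci[2])
}

# Two-way crossed ANOVA sums of squares for an n x 2 table.
.icc_mean_squares <- function(t1, t2) {
  n <- length(t1)
  m1 <- mean(t1); m2 <- mean(t2); m <- (m1 + m2) / 2
  s <- (t1 + t2) / 2
  ssr <- 2 * sum((s - m)^2)
  ssc <- n * ((m1 - m)^2 + (m2 - m)^2)
  sst <- sum((t1 - m)^2) + sum((t2 - m)^2)
  sse <- max(sst - ssr - ssc, 0)
  list(msr = ssr / (n - 1), msc = ssc, mse = sse / (n - 1), sst = sst)
}

.icc_a1_ci <- function(icc, msr, msc, mse, n, k, conf_level) {
  if (n < 3 || !is.finite(icc) || icc >= 1 || mse <= 0)
    return(c(NA_real_, NA_real_))
  alpha <- 1 - conf_level
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- stats::qf(1 - alpha / 2, df1 = n - 1, df2 = v)
  fu <- stats::qf(1 - alpha / 2, df1 = v, df2 = n - 1)
  low <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  high <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  c(low, high)
}

# Variance below this is treated as exactly zero (degenerate table).
.zero_var_tol <- function(x) 1e-18 * (1 + mean(x)^2) * length(x)

#' Worst-case aggregation of per-cohort ICCs (or paired-t p-values)
#'
#' The minimum across cohorts summarises a probe by its poorest agreement.
#' An undefined (NA) input propagates: the minimum is undefined if any
#' cohort's coefficient is.
#'
#' @param iccs numeric vector of per-cohort coefficients (NA = undefined).
#' @return Minimum, or NA if any input is NA.
#' @export
aggregate_min_icc <- function(iccs) {
  if (!length(iccs)) stop("no ICC values to aggregate", call. = FALSE)
  if (anyNA(iccs)) return(NA_real_)
  min(iccs)
}

#' @rdname aggregate_min_icc
#' @param ps numeric vector of per-cohort paired t-test p-values.
#' @export
aggregate_min_p <- function(ps) aggregate_min_icc(ps)

#' Paired t-test p-value for a two-timepoint probe
#'
#' Two-sided p-value on the within-subject differences t2 - t1. When the
#' differences have zero variance the statistic is undefined and `NA` is
#' returned.
#'
#' @inheritParams probe_mad
#' @return p-value in \[0,1\], or NA.
#' @export
paired_t_p <- function(t1, t2) {
  .check_paired(t1, t2, min_n = 2L)
  d <- t2 - t1
  n <- length(d)
  sd_d <- stats::sd(d)
  # exact zero only: in the noiseless-shift limit the p-value tends to 0,
  # so near-constant differences must not trip the sentinel
  if (sd_d == 0) return(NA_real_)
  tt <- mean(d) / (sd_d / sqrt(n))
  2 * stats::pt(-abs(tt), df = n - 1)
}

#' Pearson correlation between the two timepoints of a probe
#'
#' @inheritParams probe_mad
#' @return Correlation coefficient, or NA when either vector has zero
#'   variance.
#' @export
pearson_paired <- function(t1, t2) {
  .check_paired(t1, t2, min_n = 3L)
  if (stats::sd(t1) == 0 || stats::sd(t2) == 0)
    return(NA_real_)
  stats::cor(t1, t2)
}

#' Per-cohort standard deviation of beta values
#'
#' Sample SD (n - 1 denominator) over all samples of one cohort, both
#' timepoints pooled.
#'
#' @param values numeric vector of beta values.
#' @return Standard deviation.
#' @export
probe_sd <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need >= 2 values for an SD", call. = FALSE)
  stats::sd(values)
}

#' Ratio of worst-case absolute instability to population spread
#'
#' MMAD / mean SD: low values mark probes whose longitudinal change is small
#' relative to their between-subject variability.
#'
#' @param mmad maximum MAD across cohorts.
#' @param mean_sd mean of per-cohort SDs.
#' @return Ratio, or NA when `mean_sd` is zero.
#' @export
mad_sd_ratio <- function(mmad, mean_sd) {
  if (is.na(mmad) || is.na(mean_sd)) return(NA_real_)
  if (mean_sd <= 0) return(NA_real_)
  mmad / mean_sd
}

#' Cross-cohort correlation of a per-probe metric
#'
#' Pearson correlation between two per-probe metric vectors (e.g. the ICC
#' computed in two different cohorts), over pairwise-complete probes.
#'
#' @param a,b numeric vectors aligned on the same probes.
#' @return Correlation coefficient.
#' @export
metric_correlation <- function(a, b) {
  if (length(a) != length(b))
    stop("metric vectors differ in length", call. = FALSE)
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3)
    stop("need >= 3 pairwise-complete probes", call. = FALSE)
  stats::cor(a[ok], b[ok])
}

.check_paired <- function(t1, t2, min_n) {
  if (length(t1) != length(t2))
    stop("t1 and t2 differ in length", call. = FALSE)
  if (anyNA(t1) || anyNA(t2))
    stop("paired values must be pairwise complete (remove NA pairs first)",
         call. = FALSE)
  if (length(t1) < min_n)
    stop(sprintf("need >= %d paired subjects, got %d", min_n, length(t1)),
         call. = FALSE)
  invisible(TRUE)
}

#' Timepoint matrices for a cohort, with replicate collapsing
#'
#' Maps a cohort's beta matrix and study design to two aligned probes x
#' subjects matrices (timepoint 1 and 2). Technical replicates for one
#' (subject, timepoint) are averaged by default or reduced to the first
#' sample (file order) with `replicates = "drop"`.
#'
#' @param beta a [beta_matrix()].
#' @param design a `study_design`.
#' @param replicates "average" or "drop".
#' @return List with matrices `t1`, `t2` (columns = subjects).
#' @export
paired_matrices <- function(beta, design, replicates = c("average", "drop")) {
  replicates <- match.arg(replicates)
  sm <- design$samples
  missing_samp <- setdiff(sm$sample_id, sample_ids(beta))
  if (length(missing_samp))
    stop("cohort ", design$cohort_id, ": sample(s) not in beta matrix: ",
         paste(missing_samp, collapse = ", "), call. = FALSE)
  one_tp <- function(tp) {
    rows <- sm[sm$timepoint == tp, , drop = FALSE]
    if (replicates == "drop")
      rows <- rows[!duplicated(rows$subject_id), , drop = FALSE]
    v <- beta$values[, rows$sample_id, drop = FALSE]
    grp <- factor(rows$subject_id, levels = design$subjects)
    # rowsum aggregates replicate columns; NA-aware mean via counts
    cnt <- t(rowsum(t(!is.na(v)) + 0, grp))
    tot <- t(rowsum(t(ifelse(is.na(v), 0, v)), grp))
    out <- tot / cnt
    out[cnt == 0] <- NA_real_
    colnames(out) <- design$subjects
    out
  }
  list(t1 = one_tp(1L), t2 = one_tp(2L))
}

# Vectorised per-probe paired metrics over aligned probes x subjects
# matrices. Pairs with a missing value at either timepoint are removed per
# probe; probes with fewer than `min_pairs_icc` complete pairs get NA ICC.
.paired_metrics <- function(t1, t2, conf_level = 0.95, min_pairs_icc = 3L) {
  ok <- !(is.na(t1) | is.na(t2))
  t1[!ok] <- NA; t2[!ok] <- NA
  n <- rowSums(ok)
  d <- t2 - t1
  mad <- rowMeans(abs(d), na.rm = TRUE)
  mad[n < 1] <- NA_real_

  m1 <- rowSums(t1, na.rm = TRUE) / n
  m2 <- rowSums(t2, na.rm = TRUE) / n
  m <- (m1 + m2) / 2

  # paired t
  dbar <- rowMeans(d, na.rm = TRUE)
  ss_d <- rowSums((d - dbar)^2, na.rm = TRUE)
  var_d <- ss_d / (n - 1)
  tstat <- dbar / sqrt(var_d / n)
  t_p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  t_p[n < 2 | ss_d == 0] <- NA_real_

  # pearson
  ss1 <- rowSums((t1 - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((t2 - m2)^2, na.rm = TRUE)
  sxy <- rowSums((t1 - m1) * (t2 - m2), na.rm = TRUE)
  r <- sxy / sqrt(ss1 * ss2)
  r[n < 3 | ss1 == 0 | ss2 == 0] <- NA_real_

  # ICC(A,1), k = 2
  k <- 2
  s <- (t1 + t2) / 2
  ssr <- 2 * rowSums((s - m)^2, na.rm = TRUE)
  ssc <- n * ((m1 - m)^2 + (m2 - m)^2)
  sst <- rowSums((t1 - m)^2, na.rm = TRUE) + rowSums((t2 - m)^2, na.rm = TRUE)
  sse <- pmax(sst - ssr - ssc, 0)
  msr <- ssr / (n - 1)
  msc <- ssc
  mse <- sse / (n - 1)
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  tol_t <- 1e-18 * (1 + m^2) * 2 * n
  icc[n < min_pairs_icc | sst <= tol_t] <- NA_real_

  ci <- .icc_a1_ci_vec(icc, msr, msc, mse, n, k, conf_level)

  data.frame(n_pairs = n, mad = mad, icc = icc,
             icc_low = ci$low, icc_high = ci$high,
             pearson = r, t_p = t_p)
}

.icc_a1_ci_vec <- function(icc, msr, msc, mse, n, k, conf_level) {
  alpha <- 1 - conf_level
  bad <- is.na(icc) | n < 3 | icc >= 1 | mse <= 0
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  v[bad] <- 1  # placeholder; masked below
  fl <- stats::qf(1 - alpha / 2, df1 = pmax(n - 1, 1), df2 = v)
  fu <- stats::qf(1 - alpha / 2, df1 = v, df2 = pmax(n - 1, 1))
  low <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  high <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  low[bad] <- NA_real_; high[bad] <- NA_real_
  list(low = low, high = high)
}

#' Per-probe stability table across cohorts
#'
#' Computes, for every probe shared by all cohorts: MAD, ICC(A,1) with 95%
#' CI, Pearson r and the paired-t p-value per cohort; the pooled per-cohort
#' SD; and the cross-cohort aggregates MMAD (max MAD), min ICC, min paired-t
#' p, mean SD and MMAD / mean SD. Technical replicates are collapsed per
#' (subject, timepoint) before pairing; missing values are removed pairwise
#' per probe per cohort; probes with fewer than 3 complete pairs in a cohort
#' get an undefined (NA) ICC there, and undefined values propagate through
#' the min aggregates.
#'
#' @param cohorts list of `list(beta = , design = )`, probes already
#'   harmonized to a common set (see [harmonize_probes()]).
#' @param replicates replicate handling, see [paired_matrices()].
#' @param conf_level confidence level for ICC intervals.
#' @return data.frame (class `stability_table`) with one row per probe:
#'   probe_id, per-cohort columns suffixed by cohort ID, and the aggregate
#'   columns mmad, min_icc, min_t_p, mean_sd, mad_sd_ratio.
#' @export
compute_stability_table <- function(cohorts, replicates = "average",
                                    conf_level = 0.95) {
  if (!length(cohorts)) stop("no cohorts supplied", call. = FALSE)
  probes <- probe_ids(cohorts[[1]]$beta)
  for (co in cohorts[-1]) {
    if (!identical(probe_ids(co$beta), probes))
      stop("cohorts are not probe-harmonized; run harmonize_probes() first",
           call. = FALSE)
  }
  if (!length(probes)) stop("no shared probes", call. = FALSE)

  out <- data.frame(probe_id = probes, stringsAsFactors = FALSE)
  mad_m <- icc_m <- tp_m <- sd_m <- mean_m <- NULL
  for (co in cohorts) {
    cid <- co$design$cohort_id
    pm <- paired_matrices(co$beta, co$design, replicates)
    met <- .paired_metrics(pm$t1, pm$t2, conf_level)
    pooled <- cbind(pm$t1, pm$t2)
    nn <- rowSums(!is.na(pooled))
    mu <- rowMeans(pooled, na.rm = TRUE)
    sdv <- sqrt(rowSums((pooled - mu)^2, na.rm = TRUE) / (nn - 1))
    sdv[nn < 2] <- NA_real_
    mu[nn < 1] <- NA_real_
    out[[paste0("mad_", cid)]] <- met$mad
    out[[paste0("icc_", cid)]] <- met$icc
    out[[paste0("icc_low_", cid)]] <- met$icc_low
    out[[paste0("icc_high_", cid)]] <- met$icc_high
    out[[paste0("pearson_", cid)]] <- met$pearson
    out[[paste0("t_p_", cid)]] <- met$t_p
    out[[paste0("sd_", cid)]] <- sdv
    mad_m <- cbind(mad_m, met$mad)
    icc_m <- cbind(icc_m, met$icc)
    tp_m <- cbind(tp_m, met$t_p)
    sd_m <- cbind(sd_m, sdv)
    mean_m <- cbind(mean_m, mu)
  }
  out$mmad <- apply(mad_m, 1, max)
  out$min_icc <- .min_propagate_na(icc_m)
  out$min_t_p <- .min_propagate_na(tp_m)
  out$mean_sd <- rowMeans(sd_m)
  out$mean_beta <- rowMeans(mean_m)
  out$mad_sd_ratio <- ifelse(is.na(out$mean_sd) | out$mean_sd <= 0,
                             NA_real_, out$mmad / out$mean_sd)
  attr(out, "cohort_ids") <- vapply(cohorts, function(co) co$design$cohort_id,
                                    character(1))
  class(out) <- c("stability_table", "data.frame")
  out
}

.min_propagate_na <- function(m) {
  res <- apply(m, 1, min)      # NA if any entry NA
  as.numeric(res)
}
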