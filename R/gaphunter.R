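#' Segment sorted beta values at gaps
#'
#' Sorts the values ascending and opens a new group wherever the difference
#' between consecutive sorted values is >= `gap_threshold` (ties at the
#' threshold split, so behaviour at the boundary is deterministic). Discrete
#' groups in a probe's beta distribution typically reflect underlying
#' genotype (unmethylated / hemi / fully methylated alleles).
#'
#' @param values numeric vector of beta values; NAs are ignored.
#' @param gap_threshold minimum beta difference that opens a gap.
#' @return Integer vector of group sizes in ascending-value order.
#' @export
segment_by_gaps <- function(values, gap_threshold = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 2)
    stop("need >= 2 non-missing values to segment", call. = FALSE)
  if (gap_threshold <= 0 || gap_threshold >= 1)
    stop("gap_threshold must lie in (0, 1)", call. = FALSE)
  v <- sort(values)
  brk <- diff(v) >= gap_threshold
  grp <- cumsum(c(0L, brk))
  as.integer(tabulate(grp + 1L))
}

#' Gap call for a single probe
#'
#' A probe "has a gap" when segmentation yields two or more groups, unless
#' the split is driven by outliers: the call is suppressed (with
#' `drop_outlier_probes = TRUE`) when the samples outside the largest group
#' together number fewer than `ceiling(out_cutoff * n)`.
#'
#' @inheritParams segment_by_gaps
#' @param out_cutoff minimum proportion of samples outside the largest group
#'   for a multi-group probe to count as a genuine gap signal.
#' @param drop_outlier_probes suppress outlier-driven calls?
#' @return List with `has_gap`, `n_groups`, `group_sizes`, `outlier_driven`.
#' @export
gap_call_probe <- function(values, gap_threshold = 0.05, out_cutoff = 0.01,
                           drop_outlier_probes = TRUE) {
  sizes <- segment_by_gaps(values, gap_threshold)
  n <- sum(sizes)
  n_groups <- length(sizes)
  outlier_driven <- n_groups >= 2 &&
    (n - max(sizes)) < ceiling(out_cutoff * n)
  list(has_gap = n_groups >= 2 && !(outlier_driven && drop_outlier_probes),
       n_groups = n_groups,
       group_sizes = sizes,
       outlier_driven = outlier_driven)
}

#' Gap calls for every probe of a cohort
#'
#' Applies [gap_call_probe()] to each probe using all samples of the cohort,
#' both timepoints pooled (gap structure is a population property, not a
#' longitudinal one).
#'
#' @param beta a [beta_matrix()].
#' @inheritParams gap_call_probe
#' @return data.frame with columns probe_id, has_gap, n_groups, group_sizes
#'   (comma-joined), outlier_driven.
#' @export
gap_call_cohort <- function(beta, gap_threshold = 0.05, out_cutoff = 0.01,
                            drop_outlier_probes = TRUE) {
  v <- beta$values
  if (ncol(v) < 2) stop("need >= 2 samples for gap calling", call. = FALSE)
  calls <- lapply(seq_len(nrow(v)), function(i)
    gap_call_probe(v[i, ], gap_threshold, out_cutoff, drop_outlier_probes))
  data.frame(
    probe_id = rownames(v),
    has_gap = vapply(calls, `[[`, TRUE, "has_gap"),
    n_groups = vapply(calls, `[[`, 1L, "n_groups"),
    group_sizes = vapply(calls, function(x)
      paste(x$group_sizes, collapse = ","), character(1)),
    outlier_driven = vapply(calls, `[[`, TRUE, "outlier_driven"),
    stringsAsFactors = FALSE)
}
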