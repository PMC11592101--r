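#' Detection p-value filtering for one cohort
#'
#' Stage 1 (probe level): with `probe_rule = "any_sample"` a probe fails if
#' any sample's detection p-value exceeds `p_cut`; with "max_fraction" it
#' fails only if more than `max_fail_fraction` of samples exceed the cut.
#' Stage 2 (sample level): after probe removal, samples whose mean
#' detection p-value over retained probes exceeds `sample_mean_p_cut` are
#' dropped. The published wording for the probe rule is ambiguous between
#' the two readings; "any_sample" is the strictest and the default.
#'
#' @param beta a [beta_matrix()] with detection p-values attached.
#' @param p_cut per-cell detection p-value cut.
#' @param probe_rule "any_sample" or "max_fraction".
#' @param max_fail_fraction tolerated failing-sample fraction under
#'   "max_fraction".
#' @param sample_mean_p_cut mean detection p cut for sample removal.
#' @return List: `beta` (filtered), `report` (counts per stage:
#'   probes_in/probes_removed/probes_out, samples_in/samples_removed/
#'   samples_out, removed_probes, removed_samples).
#' @export
filter_by_detection <- function(beta, p_cut = 0.01,
                                probe_rule = c("any_sample", "max_fraction"),
                                max_fail_fraction = 0.05,
                                sample_mean_p_cut = 0.01) {
  probe_rule <- match.arg(probe_rule)
  if (is.null(beta$detection_p))
    stop("detection filtering requested but no detection p-values present",
         call. = FALSE)
  p <- beta$detection_p
  fail <- !is.na(p) & p > p_cut
  probe_bad <- if (probe_rule == "any_sample") {
    rowSums(fail) > 0
  } else {
    rowMeans(fail) > max_fail_fraction
  }
  kept <- beta
  if (any(probe_bad))
    kept <- subset_beta(beta, probes = which(!probe_bad))
  sample_bad <- colMeans(kept$detection_p, na.rm = TRUE) > sample_mean_p_cut
  out <- if (any(sample_bad)) subset_beta(kept, samples = which(!sample_bad)) else kept
  list(beta = out,
       report = list(
         probes_in = nrow(beta$values),
         probes_removed = sum(probe_bad),
         probes_out = nrow(out$values),
         samples_in = ncol(beta$values),
         samples_removed = sum(sample_bad),
         samples_out = ncol(out$values),
         removed_probes = rownames(beta$values)[probe_bad],
         removed_samples = colnames(beta$values)[sample_bad]))
}

#' Column quantile normalization of a cohort's beta values
#'
#' Classic quantile normalization within a cohort: each sample's values are
#' replaced by the across-sample mean of order statistics at their rank, so
#' all samples share one empirical distribution; ties receive the mean of
#' the values they span. Missing cells are imputed with the per-probe
#' median for the normalization and restored to missing afterwards. The
#' mapping itself is delegated to limma's implementation of this standard
#' transform.
#'
#' @param beta a [beta_matrix()] (>= 2 samples).
#' @return A [beta_matrix()] with normalized values (detection p-values
#'   carried through unchanged).
#' @export
quantile_normalize <- function(beta) {
  v <- beta$values
  if (ncol(v) < 2)
    stop("quantile normalization needs >= 2 samples", call. = FALSE)
  na_mask <- is.na(v)
  if (any(na_mask)) {
    med <- apply(v, 1, stats::median, na.rm = TRUE)
    idx <- which(na_mask, arr.ind = TRUE)
    v[na_mask] <- med[idx[, 1]]
    if (anyNA(v))
      stop("probe(s) with all values missing cannot be normalized",
           call. = FALSE)
  }
  norm <- limma::normalizeQuantiles(v, ties = TRUE)
  norm[na_mask] <- NA_real_
  dimnames(norm) <- dimnames(beta$values)
  # mean order statistics of values in [0,1] stay in [0,1]
  beta_matrix(norm, beta$detection_p)
}

#' Restrict cohorts to their common probe set
#'
#' Replaces array-level merging: every cohort matrix is subset to the
#' sorted intersection of probe IDs (e.g. the 450k subset when EPIC and
#' 450k cohorts are mixed).
#'
#' @param betas list of [beta_matrix()] objects.
#' @return List with `betas` (harmonized, common sorted probe order) and
#'   `report` (common probe count, per-cohort probes dropped).
#' @export
harmonize_probes <- function(betas) {
  if (!length(betas)) stop("no cohorts supplied", call. = FALSE)
  common <- Reduce(intersect, lapply(betas, probe_ids))
  if (!length(common)) stop("no probes shared across cohorts", call. = FALSE)
  common <- sort(common)
  dropped <- vapply(betas, function(b) nrow(b$values) - length(common), 1L)
  list(betas = lapply(betas, subset_beta, probes = common),
       report = list(n_common = length(common), dropped_per_cohort = dropped))
}

#' Pipeline configuration
#'
#' @param beta_paths named character vector of per-cohort beta TSVs (names
#'   are cohort IDs matching the sample sheet).
#' @param detection_paths aligned detection p-value TSVs (optional; required
#'   when `filter_detection`).
#' @param sample_sheet_path combined sample sheet CSV.
#' @param manifest_path manifest-style annotation CSV.
#' @param snp_col SNP indicator column in the manifest.
#' @param filter_detection apply detection filtering?
#' @param detection_p_cut,probe_rule,max_fail_fraction,sample_mean_p_cut see
#'   [filter_by_detection()].
#' @param do_quantile_normalize quantile-normalize each cohort before
#'   metrics?
#' @param gap_threshold,out_cutoff,drop_outlier_probes see
#'   [gap_call_probe()].
#' @param classification a [classification_config()].
#' @param replicates replicate handling ("average" or "drop").
#' @param batch_corrected attestation that inputs are already
#'   batch-corrected (recorded in the report; no correction is performed).
#' @param out_dir output directory for the result files.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(beta_paths, detection_paths = NULL,
                            sample_sheet_path, manifest_path,
                            snp_col = "Probe_SNPs",
                            filter_detection = !is.null(detection_paths),
                            detection_p_cut = 0.01,
                            probe_rule = "any_sample",
                            max_fail_fraction = 0.05,
                            sample_mean_p_cut = 0.01,
                            do_quantile_normalize = TRUE,
                            gap_threshold = 0.05, out_cutoff = 0.01,
                            drop_outlier_probes = TRUE,
                            classification = classification_config(),
                            replicates = "average",
                            batch_corrected = TRUE,
                            out_dir) {
  if (is.null(names(beta_paths)))
    stop("beta_paths must be named by cohort ID", call. = FALSE)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full stability pipeline
#'
#' Reads the cohorts, then: harmonizes probes to the common set; applies
#' detection filtering (a probe failing in any cohort is dropped from all;
#' samples failing the mean-p rule are dropped along with their subject's
#' pair); optionally quantile-normalizes each cohort; computes the
#' stability table; gap-calls each cohort; combines SNP flags and gap calls
#' into the genetic-influence flag; derives MMAD / min-ICC cuts and
#' classifies probes. Writes the stability+category TSV, per-cohort
#' gap-call TSVs and a JSON summary report. Deterministic given fixed
#' inputs.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with `table` (stability + categories),
#'   `summary` (the report), and `paths` of written files.
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort_ids <- names(config$beta_paths)

  betas <- lapply(cohort_ids, function(cid)
    read_beta_matrix(config$beta_paths[[cid]],
                     if (!is.null(config$detection_paths))
                       config$detection_paths[[cid]] else NULL))
  names(betas) <- cohort_ids
  designs <- read_sample_sheet(config$sample_sheet_path)
  miss <- setdiff(cohort_ids, names(designs))
  if (length(miss))
    stop("sample sheet lacks cohort(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  designs <- designs[cohort_ids]
  annotation <- read_manifest(config$manifest_path, snp_col = config$snp_col)

  harm <- harmonize_probes(betas)
  betas <- harm$betas
  stage_counts <- list(harmonize = harm$report)

  if (isTRUE(config$filter_detection)) {
    filt <- lapply(betas, filter_by_detection,
                   p_cut = config$detection_p_cut,
                   probe_rule = config$probe_rule,
                   max_fail_fraction = config$max_fail_fraction,
                   sample_mean_p_cut = config$sample_mean_p_cut)
    # a probe failing in any cohort is dropped from all cohorts
    bad_union <- unique(unlist(lapply(filt, function(f)
      f$report$removed_probes)))
    betas <- lapply(filt, function(f) {
      keep <- setdiff(probe_ids(f$beta), bad_union)
      subset_beta(f$beta, probes = keep)
    })
    designs <- mapply(function(d, f) {
      if (!length(f$report$removed_samples)) return(d)
      keep <- !(d$samples$sample_id %in% f$report$removed_samples)
      study_design(d$cohort_id, d$samples[keep, , drop = FALSE])
    }, designs, filt, SIMPLIFY = FALSE)
    stage_counts$detection <- lapply(filt, function(f)
      f$report[c("probes_in", "probes_removed", "samples_in",
                 "samples_removed")])
    stage_counts$detection_union <- list(
      probes_removed_union = length(bad_union),
      probes_out = nrow(betas[[1]]$values))
  }

  if (isTRUE(config$do_quantile_normalize))
    betas <- lapply(betas, quantile_normalize)

  cohorts <- mapply(function(b, d) list(beta = b, design = d),
                    betas, designs, SIMPLIFY = FALSE)
  table <- compute_stability_table(cohorts, replicates = config$replicates)

  gap_calls <- lapply(betas, gap_call_cohort,
                      gap_threshold = config$gap_threshold,
                      out_cutoff = config$out_cutoff,
                      drop_outlier_probes = config$drop_outlier_probes)

  ann_sub <- annotation[annotation$probe_id %in% table$probe_id, , drop = FALSE]
  gen <- genetic_influence(ann_sub, gap_calls)
  cuts <- percentile_thresholds(table, config$classification)
  categories <- classify_probes(table, gen$genetic, cuts,
                                config$classification)
  full <- merge(table, categories, by = "probe_id", sort = TRUE)

  metric_cors <- .cross_cohort_correlations(table, cohort_ids)

  summary <- list(
    cohorts = cohort_ids,
    n_subjects = vapply(designs, function(d) length(d$subjects), 1L),
    stage_counts = stage_counts,
    probe_rule_note = paste(
      "Probe-level detection rule applied as", config$probe_rule,
      "; the alternative reading (max_fraction) is available in the config."),
    batch_corrected = isTRUE(config$batch_corrected),
    cuts = cuts,
    mmad_median = stats::median(table$mmad, na.rm = TRUE),
    mmad_iqr = unname(stats::quantile(table$mmad, c(0.25, 0.75),
                                      na.rm = TRUE)),
    min_icc_median = stats::median(table$min_icc, na.rm = TRUE),
    min_icc_iqr = unname(stats::quantile(table$min_icc, c(0.25, 0.75),
                                         na.rm = TRUE)),
    n_genetic = sum(categories$genetic),
    n_hyperstable = sum(categories$hyperstable),
    n_hyperstable_nongenetic = sum(categories$hyperstable_nongenetic),
    n_invariant = sum(categories$invariant),
    genetic_summary = gen$summary,
    metric_correlations = metric_cors)

  paths <- list(
    stability = file.path(out_dir, "stability_table.tsv"),
    summary = file.path(out_dir, "summary.json"))
  write_stability_table(full, paths$stability)
  for (cid in cohort_ids) {
    p <- file.path(out_dir, paste0("gap_calls_", cid, ".tsv"))
    gc_tab <- gap_calls[[cid]][order(gap_calls[[cid]]$probe_id), ]
    gc_tab$has_gap <- as.integer(gc_tab$has_gap)
    gc_tab$outlier_driven <- as.integer(gc_tab$outlier_driven)
    data.table::fwrite(gc_tab, p, sep = "\t")
    paths[[paste0("gap_calls_", cid)]] <- p
  }
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(table = full, summary = summary, paths = paths))
}

.cross_cohort_correlations <- function(table, cohort_ids) {
  if (length(cohort_ids) < 2) return(NULL)
  prs <- utils::combn(cohort_ids, 2, simplify = FALSE)
  out <- list()
  for (pr in prs) {
    key <- paste(pr, collapse = "_vs_")
    out[[paste0("icc_", key)]] <-
      metric_correlation(table[[paste0("icc_", pr[1])]],
                         table[[paste0("icc_", pr[2])]])
    out[[paste0("mad_", key)]] <-
      metric_correlation(table[[paste0("mad_", pr[1])]],
                         table[[paste0("mad_", pr[2])]])
  }
  out
}
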