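#' Flag probes under genetic influence
#'
#' A probe is considered genetically influenced when the array manifest
#' flags a SNP near its target site or when gap segmentation calls it in
#' any cohort. The summary reports the set sizes entering the union so that
#' inclusion-exclusion can be checked exactly:
#' |SNP or gap| = |SNP| + |gap union| - |SNP and gap union|.
#'
#' @param annotation a `probe_annotation` covering all probes.
#' @param gap_calls list of per-cohort gap-call data.frames from
#'   [gap_call_cohort()] (or any data.frame with probe_id and has_gap).
#' @return List with `genetic` (named logical over annotation probes) and
#'   `summary` (n_snp, gap counts per cohort, n_gap_union, n_overlap,
#'   n_union).
#' @export
genetic_influence <- function(annotation, gap_calls) {
  if (!length(gap_calls)) stop("need gap calls for >= 1 cohort", call. = FALSE)
  gap_sets <- lapply(gap_calls, function(gc) gc$probe_id[gc$has_gap])
  all_called <- unique(unlist(lapply(gap_calls, `[[`, "probe_id")))
  unknown <- setdiff(all_called, annotation$probe_id)
  if (length(unknown))
    stop("gap-called probe(s) absent from annotation: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  gap_union <- unique(unlist(gap_sets))
  snp_set <- annotation$probe_id[annotation$snp_flag]
  genetic <- annotation$snp_flag | annotation$probe_id %in% gap_union
  names(genetic) <- annotation$probe_id
  per_cohort <- vapply(gap_sets, length, 1L)
  if (is.null(names(per_cohort)) || any(names(per_cohort) == ""))
    names(per_cohort) <- paste0("cohort", seq_along(per_cohort))
  list(genetic = genetic,
       summary = list(
         n_snp = length(snp_set),
         n_gap_per_cohort = per_cohort,
         n_gap_union = length(gap_union),
         n_overlap = length(intersect(snp_set, gap_union)),
         n_union = length(union(snp_set, gap_union))))
}

#' Classification thresholds for hyperstability
#'
#' Configuration for [percentile_thresholds()] and [classify_probes()].
#' Percentile cuts default to the 5th percentile of MMAD and the 95th
#' percentile of the minimum ICC; supplying `fixed_mmad_cut` /
#' `fixed_icc_cut` (e.g. the published 0.01 and 0.74) overrides the
#' empirical quantiles.
#'
#' @param mmad_percentile probability for the MMAD cut.
#' @param icc_percentile probability for the min-ICC cut.
#' @param fixed_mmad_cut optional fixed MMAD cut (beta fraction).
#' @param fixed_icc_cut optional fixed min-ICC cut.
#' @param invariance_sd_cut mean-SD cut below which a probe is flagged
#'   invariant.
#' @param extreme_mean_invariance additionally require the probe's mean beta
#'   outside \[0.2, 0.8\] for the invariant flag (off by default).
#' @param exclude_genetic report hyperstable probes net of genetic influence.
#' @return List of class `classification_config`.
#' @export
classification_config <- function(mmad_percentile = 0.05,
                                  icc_percentile = 0.95,
                                  fixed_mmad_cut = NULL,
                                  fixed_icc_cut = NULL,
                                  invariance_sd_cut = 0.1,
                                  extreme_mean_invariance = FALSE,
                                  exclude_genetic = TRUE) {
  stopifnot(mmad_percentile > 0, mmad_percentile < 1,
            icc_percentile > 0, icc_percentile < 1,
            invariance_sd_cut > 0)
  structure(list(mmad_percentile = mmad_percentile,
                 icc_percentile = icc_percentile,
                 fixed_mmad_cut = fixed_mmad_cut,
                 fixed_icc_cut = fixed_icc_cut,
                 invariance_sd_cut = invariance_sd_cut,
                 extreme_mean_invariance = extreme_mean_invariance,
                 exclude_genetic = exclude_genetic),
            class = "classification_config")
}

#' Empirical MMAD / min-ICC cuts
#'
#' Quantiles use linear interpolation between order statistics (type 7).
#' Undefined (NA) metrics are excluded before the quantile is taken. Fixed
#' cuts in the config override the empirical values.
#'
#' @param table a stability table from [compute_stability_table()].
#' @param config a [classification_config()].
#' @return List with `mmad_cut` and `icc_cut`.
#' @export
percentile_thresholds <- function(table, config = classification_config()) {
  mmad <- table$mmad[!is.na(table$mmad)]
  icc <- table$min_icc[!is.na(table$min_icc)]
  if (is.null(config$fixed_mmad_cut) && !length(mmad))
    stop("all MMAD values are undefined", call. = FALSE)
  if (is.null(config$fixed_icc_cut) && !length(icc))
    stop("all min-ICC values are undefined", call. = FALSE)
  list(
    mmad_cut = config$fixed_mmad_cut %||%
      unname(stats::quantile(mmad, config$mmad_percentile, type = 7)),
    icc_cut = config$fixed_icc_cut %||%
      unname(stats::quantile(icc, config$icc_percentile, type = 7)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.quadrant_levels <- c("lowMMAD_highICC", "lowMMAD_lowICC",
                      "highMMAD_highICC", "highMMAD_lowICC")

#' Classify probes into stability categories
#'
#' Hyperstable probes satisfy MMAD strictly below the MMAD cut and min ICC
#' strictly above the ICC cut; `hyperstable_nongenetic` additionally
#' requires no genetic influence. The same two cuts define the four
#' MMAD x ICC quadrants. Probes with an undefined MMAD or min ICC get no
#' quadrant and cannot be hyperstable. The invariant flag marks probes whose
#' between-subject spread (mean SD) falls below `invariance_sd_cut`,
#' optionally restricted to extreme mean methylation.
#'
#' @param table stability table.
#' @param genetic named logical vector from [genetic_influence()] (or any
#'   logical aligned on `table$probe_id`).
#' @param cuts list with `mmad_cut`, `icc_cut` from
#'   [percentile_thresholds()].
#' @param config a [classification_config()].
#' @return data.frame: probe_id, genetic, hyperstable,
#'   hyperstable_nongenetic, quadrant (NA when undefined), invariant.
#' @export
classify_probes <- function(table, genetic, cuts,
                            config = classification_config()) {
  if (!is.null(names(genetic))) {
    miss <- setdiff(table$probe_id, names(genetic))
    if (length(miss))
      stop("genetic flags missing for probe(s): ",
           paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
    genetic <- unname(genetic[table$probe_id])
  } else if (length(genetic) != nrow(table)) {
    stop("genetic flag vector not aligned with table", call. = FALSE)
  }
  defined <- !is.na(table$mmad) & !is.na(table$min_icc)
  low_mmad <- defined & table$mmad < cuts$mmad_cut
  high_icc <- defined & table$min_icc > cuts$icc_cut
  quadrant <- rep(NA_character_, nrow(table))
  quadrant[defined] <- paste0(
    ifelse(low_mmad[defined], "lowMMAD_", "highMMAD_"),
    ifelse(high_icc[defined], "highICC", "lowICC"))
  hyper <- low_mmad & high_icc
  invariant <- !is.na(table$mean_sd) & table$mean_sd < config$invariance_sd_cut
  if (isTRUE(config$extreme_mean_invariance)) {
    mean_beta <- table$mean_beta %||% rep(NA_real_, nrow(table))
    invariant <- invariant & !is.na(mean_beta) &
      (mean_beta < 0.2 | mean_beta > 0.8)
  }
  data.frame(probe_id = table$probe_id,
             genetic = genetic,
             hyperstable = hyper,
             hyperstable_nongenetic = hyper & !genetic,
             quadrant = quadrant,
             invariant = invariant,
             stringsAsFactors = FALSE)
}
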