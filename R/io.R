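#' Read a beta-value matrix from TSV
#'
#' The file layout is one probe per row: first column probe ID, remaining
#' columns one per sample with sample IDs in the header. Missing cells use
#' the token "NA". An optional detection p-value TSV of identical layout can
#' be attached; it must match the beta matrix cell for cell.
#'
#' @param path TSV of beta values.
#' @param detp_path optional TSV of detection p-values, same layout.
#' @return A [beta_matrix()].
#' @export
read_beta_matrix <- function(path, detp_path = NULL) {
  v <- .read_matrix_tsv(path)
  d <- NULL
  if (!is.null(detp_path)) {
    d <- .read_matrix_tsv(detp_path, check_range = FALSE)
    if (!identical(dim(d), dim(v)) || !identical(dimnames(d), dimnames(v)))
      stop("detection matrix '", detp_path,
           "' is not aligned with beta matrix '", path, "'", call. = FALSE)
  }
  beta_matrix(v, d)
}

.read_matrix_tsv <- function(path, check_range = TRUE) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = "NA", data.table = FALSE)
  if (ncol(dt) < 2) stop("'", path, "': expected probe ID + sample columns",
                         call. = FALSE)
  ids <- as.character(dt[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("'", path, "': duplicate probe ID ", dup[1], call. = FALSE)
  m <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (check_range) {
    bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("'%s': value %g outside [0,1] at probe '%s', sample '%s'",
                   path, m[bad[1, , drop = FALSE]],
                   rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]),
           call. = FALSE)
  }
  m
}

#' Write a beta-value (or detection p-value) matrix to TSV
#'
#' @param x a [beta_matrix()], or a plain numeric matrix with dimnames.
#' @param path output TSV for beta values.
#' @param detp_path optional output TSV for the detection p-values.
#' @param id_col name of the probe-ID column in the header.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(x, path, detp_path = NULL, id_col = "probe_id") {
  v <- if (inherits(x, "beta_matrix")) x$values else x
  .write_matrix_tsv(v, path, id_col)
  if (!is.null(detp_path)) {
    if (!inherits(x, "beta_matrix") || is.null(x$detection_p))
      stop("no detection p-values to write", call. = FALSE)
    .write_matrix_tsv(x$detection_p, detp_path, id_col)
  }
  invisible(path)
}

.write_matrix_tsv <- function(m, path, id_col) {
  dt <- data.table::data.table(V1 = rownames(m))
  data.table::setnames(dt, "V1", id_col)
  dt <- cbind(dt, data.table::as.data.table(m))
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
}

#' Read a sample sheet into per-cohort study designs
#'
#' The sheet is a CSV with columns `cohort_id`, `subject_id`, `sample_id`
#' and `timepoint` (1 or 2). Subjects missing either timepoint are dropped
#' with a warning; extra samples for one (subject, timepoint) are kept as
#' technical replicates and collapsed later by [paired_matrices()].
#'
#' @param path CSV file.
#' @return Named list of `study_design` objects, one per cohort, each a list
#'   with `cohort_id`, `samples` (data.frame subject_id/timepoint/sample_id)
#'   and `subjects` (subjects complete at both timepoints).
#' @export
read_sample_sheet <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          colClasses = "character")
  need <- c("cohort_id", "subject_id", "sample_id", "timepoint")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(dt$timepoint), c("1", "2"))
  if (length(bad))
    stop("unknown timepoint token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  designs <- lapply(split(dt, dt$cohort_id), function(co) {
    study_design(co$cohort_id[1],
                 data.frame(subject_id = co$subject_id,
                            timepoint = as.integer(co$timepoint),
                            sample_id = co$sample_id,
                            stringsAsFactors = FALSE))
  })
  if (!length(designs) || !any(vapply(designs, function(d) length(d$subjects) > 0, TRUE)))
    stop("sample sheet yields no complete subject pairs", call. = FALSE)
  designs[order(names(designs))]
}

#' Construct a paired two-timepoint study design
#'
#' @param cohort_id cohort label.
#' @param samples data.frame with columns subject_id, timepoint (1/2),
#'   sample_id.
#' @return A `study_design` object.
#' @export
study_design <- function(cohort_id, samples) {
  stopifnot(all(c("subject_id", "timepoint", "sample_id") %in% names(samples)))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id within cohort ", cohort_id, call. = FALSE)
  tp <- split(samples$timepoint, samples$subject_id)
  complete <- names(tp)[vapply(tp, function(t) all(c(1L, 2L) %in% t), TRUE)]
  incomplete <- setdiff(names(tp), complete)
  if (length(incomplete))
    warning(sprintf("cohort %s: dropping %d subject(s) lacking a timepoint: %s",
                    cohort_id, length(incomplete),
                    paste(incomplete, collapse = ", ")), call. = FALSE)
  samples <- samples[samples$subject_id %in% complete, , drop = FALSE]
  structure(list(cohort_id = cohort_id,
                 samples = samples,
                 subjects = sort(complete)),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  n_rep <- nrow(x$samples) - 2L * length(x$subjects)
  cat(sprintf("<study_design> cohort %s: %d paired subjects%s\n",
              x$cohort_id, length(x$subjects),
              if (n_rep > 0) sprintf(" (+%d replicate samples)", n_rep) else ""))
  invisible(x)
}

.refgene_vocab <- c("TSS200", "TSS1500", "5'UTR", "1stExon", "Body", "3'UTR",
                    "none")

#' Read an Illumina-manifest-style probe annotation CSV
#'
#' Expects at least the columns `IlmnID`, `CHR`, `MAPINFO`,
#' `UCSC_RefGene_Name`, `UCSC_RefGene_Group`, `Infinium_Design_Type` and an
#' SNP indicator column. Multi-entry RefGene fields (semicolon-separated)
#' are collapsed to their first entry; empty groups map to "none". Any
#' non-empty value in the SNP column sets `snp_flag` — the manifest's
#' distance/allele details are not modelled.
#'
#' @param path manifest CSV.
#' @param snp_col name of the SNP indicator column (manifests differ; the
#'   450k v1.2 file carries Probe_SNPs / Probe_SNPs_10).
#' @return A `probe_annotation` data.frame with columns probe_id, chromosome,
#'   coordinate (1-based), gene, refgene_group, design_type, snp_flag.
#' @export
read_manifest <- function(path, snp_col = "Probe_SNPs") {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          colClasses = "character")
  need <- c("IlmnID", "CHR", "MAPINFO", "UCSC_RefGene_Name",
            "UCSC_RefGene_Group", "Infinium_Design_Type", snp_col)
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("manifest missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  first_entry <- function(x) {
    x <- vapply(strsplit(x, ";", fixed = TRUE),
                function(p) if (length(p)) p[1] else "", character(1))
    x[is.na(x)] <- ""
    x
  }
  grp <- first_entry(dt$UCSC_RefGene_Group)
  grp[grp == ""] <- "none"
  bad <- setdiff(unique(grp), .refgene_vocab)
  if (length(bad))
    stop("unknown RefGene group(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  snp <- dt[[snp_col]]
  ann <- data.frame(probe_id = dt$IlmnID,
                    chromosome = dt$CHR,
                    coordinate = as.integer(dt$MAPINFO),
                    gene = first_entry(dt$UCSC_RefGene_Name),
                    refgene_group = grp,
                    design_type = dt$Infinium_Design_Type,
                    snp_flag = !is.na(snp) & snp != "",
                    stringsAsFactors = FALSE)
  if (anyDuplicated(ann$probe_id))
    stop("manifest contains duplicate probe IDs", call. = FALSE)
  class(ann) <- c("probe_annotation", "data.frame")
  ann
}

# Canonical column order of the serialized stability table. Per-cohort blocks
# are expanded in cohort order at write time.
.stab_fixed_cols <- c("probe_id", "mmad", "min_icc", "min_t_p", "mean_sd",
                      "mean_beta", "mad_sd_ratio")

#' Write a per-probe stability table to TSV
#'
#' Rows are written in canonical (sorted probe ID) order so that output is
#' independent of the input probe order. Logical columns are serialized as
#' 0/1; floats keep full precision (>= 6 significant digits).
#'
#' @param table data.frame as produced by [compute_stability_table()],
#'   possibly with classification columns appended.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_stability_table <- function(table, path) {
  stopifnot("probe_id" %in% names(table))
  tab <- table[order(table$probe_id), , drop = FALSE]
  lead <- intersect(.stab_fixed_cols, names(tab))
  tab <- tab[, c(lead, setdiff(names(tab), lead)), drop = FALSE]
  for (j in seq_along(tab)) if (is.logical(tab[[j]])) tab[[j]] <- as.integer(tab[[j]])
  data.table::fwrite(tab, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read back a serialized stability table
#'
#' @param path TSV written by [write_stability_table()].
#' @return data.frame.
#' @export
read_stability_table <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA",
                    data.table = FALSE)
}
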