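#' Beta-value matrix with optional detection p-values
#'
#' A `beta_matrix` holds methylation beta values (fraction of methylated
#' signal, in \[0,1\]) for a set of array probes (rows) measured in a set of
#' samples (columns), optionally paired with a detection p-value matrix of
#' identical shape used for quality filtering.
#'
#' @param values numeric matrix, probes x samples, with unique rownames
#'   (probe IDs) and colnames (sample IDs); entries in \[0,1\] or `NA`.
#' @param detection_p optional numeric matrix of detection p-values with the
#'   same dimensions and dimnames as `values`.
#' @return An object of class `beta_matrix`: a list with elements `values`
#'   and `detection_p` (`NULL` when absent).
#' @export
beta_matrix <- function(values, detection_p = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have probe rownames and sample colnames", call. = FALSE)
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicate probe IDs: ", paste(unique(dup), collapse = ", "), call. = FALSE)
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup))
    stop("duplicate sample IDs: ", paste(unique(dup), collapse = ", "), call. = FALSE)
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "beta value out of [0,1] at probe '%s', sample '%s' (value %g)",
      rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]],
      values[bad[1, , drop = FALSE]]), call. = FALSE)
  }
  if (!is.null(detection_p)) {
    if (!is.matrix(detection_p) || !identical(dim(detection_p), dim(values)))
      stop("detection p-value matrix does not match beta matrix dimensions",
           call. = FALSE)
    if (!identical(dimnames(detection_p), dimnames(values)))
      stop("detection p-value matrix has mismatched probe/sample IDs",
           call. = FALSE)
  }
  structure(list(values = values, detection_p = detection_p),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("<beta_matrix> %d probes x %d samples%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$detection_p)) "" else " (+ detection p-values)"))
  invisible(x)
}

#' @export
dim.beta_matrix <- function(x) dim(x$values)

#' Probe and sample identifiers of a beta matrix
#' @param x a `beta_matrix`.
#' @return Character vector of IDs.
#' @export
probe_ids <- function(x) rownames(x$values)

#' @rdname probe_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Subset a beta matrix by probes and/or samples
#'
#' Keeps the detection p-value matrix aligned with the beta values.
#'
#' @param x a `beta_matrix`.
#' @param probes,samples character or integer indices; `NULL` keeps all.
#' @return A `beta_matrix`.
#' @export
subset_beta <- function(x, probes = NULL, samples = NULL) {
  v <- x$values
  d <- x$detection_p
  if (!is.null(probes)) {
    v <- v[probes, , drop = FALSE]
    if (!is.null(d)) d <- d[probes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    v <- v[, samples, drop = FALSE]
    if (!is.null(d)) d <- d[, samples, drop = FALSE]
  }
  beta_matrix(v, d)
}
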