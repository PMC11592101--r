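#' Specification for a synthetic multi-cohort methylation study
#'
#' Defines the generative model used to test the stability pipeline without
#' array data. Probes fall into four classes:
#' \describe{
#'   \item{invariant}{extreme methylation (logit mean drawn from
#'     `invariant_mu_abs`, random sign), small between- and within-subject
#'     variation; low beta-scale SD by construction.}
#'   \item{dynamic}{mid-range methylation with within-subject noise
#'     dominating: low agreement between timepoints.}
#'   \item{stable_nongenetic}{between-subject variation dominating:
#'     high agreement, small longitudinal change.}
#'   \item{genetic}{trimodal beta distribution driven by a biallelic
#'     genotype under Hardy-Weinberg proportions; genotype (hence cluster)
#'     identical at both timepoints.}
#' }
#' Nongenetic probes follow a logit-normal model: subject i, probe j has a
#' latent level u_ij ~ N(mu_j, sigma_between_j); the measurement at
#' timepoint t is inv_logit(u_ij + drift * 1[t = 2] + e_ijt) with
#' e_ijt ~ N(0, sigma_within_j). On the logit scale the population
#' agreement ICC is sigma_b^2 / (sigma_b^2 + sigma_w^2) when drift = 0,
#' which the truth table records. The inverse-logit mapping reproduces the
#' compression of variability towards the beta bounds seen on arrays.
#'
#' @param n_cohorts number of cohorts.
#' @param n_subjects subjects per cohort (two samples each).
#' @param n_probes probes shared by all cohorts.
#' @param class_fractions named proportions over invariant / dynamic /
#'   stable_nongenetic / genetic, summing to 1.
#' @param mu_range named list of logit-scale mean intervals per nongenetic
#'   class (`invariant` is the magnitude interval; sign is random).
#' @param sigma_between,sigma_within named logit-scale SDs per nongenetic
#'   class.
#' @param drift logit-scale shift applied at timepoint 2 (0 keeps the
#'   population agreement ICC equal to the variance ratio).
#' @param maf_range minor-allele-frequency interval for genetic probes,
#'   within (0, 0.5].
#' @param cluster_means ascending beta-scale means of the three genotype
#'   clusters.
#' @param cluster_noise_sd beta-scale SD around a genotype cluster mean.
#' @param snp_flag_rate_genetic probability a genetic probe carries a
#'   manifest SNP flag.
#' @param snp_flag_rate_other SNP-flag probability for nongenetic probes
#'   (real manifests flag many probes whose betas show no gap).
#' @param detection_fail_rate probability a (probe, sample) cell fails
#'   detection (p-value drawn above 0.01).
#' @param seed integer base seed; cohort c uses seed + c so cohorts are
#'   reproducible individually.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_cohorts = 3,
                           n_subjects = 60,
                           n_probes = 20000,
                           class_fractions = c(invariant = 0.20,
                                               dynamic = 0.60,
                                               stable_nongenetic = 0.05,
                                               genetic = 0.15),
                           mu_range = list(invariant = c(3.5, 5),
                                           dynamic = c(-2, 2),
                                           stable_nongenetic = c(-1.5, 1.5)),
                           sigma_between = c(invariant = 0.10,
                                             dynamic = 0.055,
                                             stable_nongenetic = 0.068),
                           sigma_within = c(invariant = 0.10,
                                            dynamic = 0.11,
                                            stable_nongenetic = 0.02),
                           drift = 0,
                           maf_range = c(0.1, 0.5),
                           cluster_means = c(0.1, 0.5, 0.9),
                           cluster_noise_sd = 0.02,
                           snp_flag_rate_genetic = 0.66,
                           snp_flag_rate_other = 0.02,
                           detection_fail_rate = 1e-4,
                           seed = 1L) {
  classes <- c("invariant", "dynamic", "stable_nongenetic", "genetic")
  if (!setequal(names(class_fractions), classes))
    stop("class_fractions must be named over: ",
         paste(classes, collapse = ", "), call. = FALSE)
  class_fractions <- class_fractions[classes]
  if (abs(sum(class_fractions) - 1) > 1e-9)
    stop("class_fractions must sum to 1", call. = FALSE)
  if (any(diff(cluster_means) <= 0) || any(cluster_means < 0) ||
      any(cluster_means > 1))
    stop("cluster_means must be strictly increasing within [0,1]",
         call. = FALSE)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]", call. = FALSE)
  structure(list(n_cohorts = n_cohorts, n_subjects = n_subjects,
                 n_probes = n_probes, class_fractions = class_fractions,
                 mu_range = mu_range, sigma_between = sigma_between,
                 sigma_within = sigma_within, drift = drift,
                 maf_range = maf_range, cluster_means = cluster_means,
                 cluster_noise_sd = cluster_noise_sd,
                 snp_flag_rate_genetic = snp_flag_rate_genetic,
                 snp_flag_rate_other = snp_flag_rate_other,
                 detection_fail_rate = detection_fail_rate,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

inv_logit <- function(x) 1 / (1 + exp(-x))

# Probe-level parameters are shared across cohorts, so they are drawn from
# the base seed alone; cohort-level draws use seed + cohort_index.
.probe_params <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_probes
  counts <- floor(spec$class_fractions * n)
  rem <- n - sum(counts)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  class <- rep(names(counts), counts)
  probe_id <- sprintf("cg%08d", seq_len(n))
  mu <- sb <- sw <- maf <- rep(NA_real_, n)
  for (cl in c("invariant", "dynamic", "stable_nongenetic")) {
    idx <- which(class == cl)
    r <- spec$mu_range[[cl]]
    mu[idx] <- stats::runif(length(idx), r[1], r[2])
    if (cl == "invariant")
      mu[idx] <- mu[idx] * sample(c(-1, 1), length(idx), replace = TRUE)
    sb[idx] <- spec$sigma_between[[cl]]
    sw[idx] <- spec$sigma_within[[cl]]
  }
  gidx <- which(class == "genetic")
  maf[gidx] <- stats::runif(length(gidx), spec$maf_range[1], spec$maf_range[2])
  snp_flag <- stats::runif(n) < ifelse(class == "genetic",
                                       spec$snp_flag_rate_genetic,
                                       spec$snp_flag_rate_other)
  true_icc <- ifelse(is.na(sb), NA_real_, sb^2 / (sb^2 + sw^2))
  data.frame(probe_id = probe_id, class = class, mu = mu,
             sigma_between = sb, sigma_within = sw, maf = maf,
             snp_flag = snp_flag, true_icc = true_icc,
             stringsAsFactors = FALSE)
}

#' Generate one synthetic cohort
#'
#' Draws paired two-timepoint beta values for every probe of the spec, plus
#' aligned detection p-values (Uniform(0, 0.005) for passing cells,
#' Uniform(0.011, 0.5) for the `detection_fail_rate` fraction that fails).
#' Probe-level parameters (class, means, MAF, SNP flags) are shared across
#' cohorts; subjects and their draws are cohort-specific. Deterministic
#' given `spec$seed` and `cohort_index`.
#'
#' @param spec a [synthetic_spec()].
#' @param cohort_index cohort number (1-based).
#' @return List with `beta` ([beta_matrix()]), `design` (`study_design`) and
#'   `truth` (data.frame: probe_id, class, true_icc, snp_flag; attribute
#'   `genotypes` holds the subject-level genotype matrix for genetic
#'   probes).
#' @export
generate_cohort <- function(spec, cohort_index) {
  pp <- .probe_params(spec)
  set.seed(spec$seed + as.integer(cohort_index))
  ns <- spec$n_subjects
  np <- spec$n_probes
  cid <- paste0("cohort", cohort_index)
  subjects <- sprintf("%s_s%03d", cid, seq_len(ns))

  b1 <- matrix(NA_real_, np, ns)
  b2 <- matrix(NA_real_, np, ns)

  ng <- which(pp$class != "genetic")
  if (length(ng)) {
    u <- pp$mu[ng] + matrix(stats::rnorm(length(ng) * ns, 0, pp$sigma_between[ng]),
                            length(ng), ns)
    e1 <- matrix(stats::rnorm(length(ng) * ns, 0, pp$sigma_within[ng]),
                 length(ng), ns)
    e2 <- matrix(stats::rnorm(length(ng) * ns, 0, pp$sigma_within[ng]),
                 length(ng), ns)
    b1[ng, ] <- inv_logit(u + e1)
    b2[ng, ] <- inv_logit(u + spec$drift + e2)
  }

  gi <- which(pp$class == "genetic")
  genotypes <- NULL
  if (length(gi)) {
    genotypes <- matrix(stats::rbinom(length(gi) * ns, 2, pp$maf[gi]),
                        length(gi), ns,
                        dimnames = list(pp$probe_id[gi], subjects))
    centre <- matrix(spec$cluster_means[genotypes + 1L], length(gi), ns)
    clip <- function(x) pmin(pmax(x, 0.001), 0.999)
    b1[gi, ] <- clip(centre + stats::rnorm(length(gi) * ns, 0,
                                           spec$cluster_noise_sd))
    b2[gi, ] <- clip(centre + stats::rnorm(length(gi) * ns, 0,
                                           spec$cluster_noise_sd))
  }

  v <- cbind(b1, b2)
  s_ids <- c(paste0(subjects, "_t1"), paste0(subjects, "_t2"))
  dimnames(v) <- list(pp$probe_id, s_ids)

  fail <- matrix(stats::runif(length(v)) < spec$detection_fail_rate,
                 nrow(v), ncol(v))
  detp <- matrix(stats::runif(length(v), 0, 0.005), nrow(v), ncol(v))
  detp[fail] <- stats::runif(sum(fail), 0.011, 0.5)
  dimnames(detp) <- dimnames(v)

  design <- study_design(cid, data.frame(
    subject_id = rep(subjects, 2),
    timepoint = rep(c(1L, 2L), each = ns),
    sample_id = s_ids,
    stringsAsFactors = FALSE))

  truth <- pp[, c("probe_id", "class", "true_icc", "snp_flag")]
  attr(truth, "genotypes") <- genotypes
  list(beta = beta_matrix(v, detp), design = design, truth = truth)
}

#' Write a full synthetic study to disk
#'
#' Generates every cohort of the spec and writes the file set the pipeline
#' reads: per-cohort beta and detection TSVs, a combined sample sheet CSV,
#' a manifest-style annotation CSV (synthetic chromosome/coordinate/gene
#' fields; SNP flags from the generator) and the ground-truth table.
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir output directory (created if needed).
#' @return Named list of written paths: `beta` and `detection` (per cohort),
#'   `sample_sheet`, `manifest`, `truth`.
#' @export
generate_study <- function(spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  beta_paths <- detp_paths <- character(0)
  sheets <- list()
  truth <- NULL
  for (ci in seq_len(spec$n_cohorts)) {
    co <- generate_cohort(spec, ci)
    cid <- co$design$cohort_id
    bp <- file.path(out_dir, paste0("beta_", cid, ".tsv"))
    dp <- file.path(out_dir, paste0("detp_", cid, ".tsv"))
    write_beta_matrix(co$beta, bp, dp)
    beta_paths[cid] <- bp
    detp_paths[cid] <- dp
    sm <- co$design$samples
    sm$cohort_id <- cid
    sheets[[cid]] <- sm[, c("cohort_id", "subject_id", "sample_id",
                            "timepoint")]
    truth <- co$truth  # probe-level truth identical across cohorts
  }
  sheet_path <- file.path(out_dir, "sample_sheet.csv")
  data.table::fwrite(data.table::rbindlist(sheets), sheet_path)

  manifest_path <- file.path(out_dir, "manifest.csv")
  data.table::fwrite(.synthetic_manifest(spec, truth), manifest_path)

  truth_path <- file.path(out_dir, "truth.tsv")
  data.table::fwrite(truth, truth_path, sep = "\t", na = "NA")

  list(beta = beta_paths, detection = detp_paths,
       sample_sheet = sheet_path, manifest = manifest_path,
       truth = truth_path)
}

# Synthetic manifest rows: positions and gene labels are placeholders; the
# SNP flag carries the generator's assignment via a dbSNP-style token.
.synthetic_manifest <- function(spec, truth) {
  set.seed(spec$seed + 10000L)
  n <- nrow(truth)
  groups <- sample(.refgene_vocab, n, replace = TRUE,
                   prob = c(.1, .1, .08, .05, .37, .08, .22))
  gene <- ifelse(groups == "none", "",
                 sprintf("GENE%05d", sample.int(9000, n, replace = TRUE)))
  data.frame(
    IlmnID = truth$probe_id,
    CHR = sample(c(as.character(1:22), "X", "Y"), n, replace = TRUE,
                 prob = c(rep(1, 22), 0.5, 0.05)),
    MAPINFO = sample.int(2e8, n, replace = TRUE),
    UCSC_RefGene_Name = gene,
    UCSC_RefGene_Group = groups,
    Infinium_Design_Type = sample(c("I", "II"), n, replace = TRUE,
                                  prob = c(0.28, 0.72)),
    Probe_SNPs = ifelse(truth$snp_flag,
                        sprintf("rs%07d", sample.int(9999999, n, replace = TRUE)),
                        ""),
    stringsAsFactors = FALSE)
}

#' Logit-scale between-subject SD needed for a target agreement ICC
#'
#' Inverts icc = sigma_b^2 / (sigma_b^2 + sigma_w^2): convenience for
#' simulation studies at fixed truth levels.
#'
#' @param icc target intraclass correlation in (0, 1).
#' @param sigma_within logit-scale within-subject SD.
#' @return sigma_between.
#' @export
sigma_between_for_icc <- function(icc, sigma_within) {
  stopifnot(icc > 0, icc < 1, sigma_within > 0)
  sigma_within * sqrt(icc / (1 - icc))
}
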