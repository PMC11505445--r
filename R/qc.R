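# Well- and sample-level quality control for OpenArray-style Cq panels.

#' Apply well-level QC criteria
#'
#' A well is retained only if its amplification score is strictly greater
#' than `min_amp_score`, its Cq confidence strictly greater than
#' `min_cq_conf`, and its Cq at least `min_cq` (inclusive floor). Failing
#' wells become QC-excluded (`"excl"`): they are treated downstream as
#' missing-not-censored, since a QC failure is a technical artifact and not
#' evidence of low abundance. Observed wells with missing QC covariates fail.
#'
#' @param ct a [ct_matrix()] with QC covariates attached
#' @param min_amp_score amplification score threshold (strict >, default 1)
#' @param min_cq_conf Cq confidence threshold (strict >, default 0.8)
#' @param min_cq Cq floor (inclusive >=, default 6)
#' @return list: `ct` (new matrix), `n_removed` (wells excluded by this call)
#' @export
apply_well_qc <- function(ct, min_amp_score = 1, min_cq_conf = 0.8,
                          min_cq = 6) {
  if (is.null(ct$amp_score) || is.null(ct$cq_confidence))
    stop("QC covariates (amp_score, cq_confidence) are required")
  obs <- ct$status == "obs"
  amp_ok <- !is.na(ct$amp_score) & ct$amp_score > min_amp_score
  conf_ok <- !is.na(ct$cq_confidence) & ct$cq_confidence > min_cq_conf
  cq_ok <- !is.na(ct$values) & ct$values >= min_cq
  fail <- obs & !(amp_ok & conf_ok & cq_ok)
  status <- ct$status
  values <- ct$values
  status[fail] <- "excl"
  values[fail] <- NA_real_
  list(ct = ct_matrix(values, status, ct$detection_limit,
                      ct$amp_score, ct$cq_confidence),
       n_removed = sum(fail))
}

#' Hemolysis screen from the miR-23a-3p / miR-451a marker pair
#'
#' Serum hemolysis releases the red-blood-cell miRNA miR-451a; the screen
#' computes, per sample, delta Cq = Cq(miR-23a-3p) - Cq(miR-451a) and accepts
#' the sample when delta Cq is strictly below `threshold` (default 8). A
#' sample with either marker missing is flagged indeterminate (`NA` pass
#' flag); whether indeterminate samples are kept is decided by the caller.
#'
#' @param ct a [ct_matrix()] (post well-QC)
#' @param samples sample table
#' @param marker_stable hemolysis-insensitive marker (default miR-23a-3p)
#' @param marker_rbc red-blood-cell marker (default miR-451a)
#' @param threshold delta Cq acceptance threshold, strict < (default 8)
#' @return `samples` with columns `hemolysis_delta_cq`, `hemolysis_pass`
#'   (`TRUE`/`FALSE`/`NA` for indeterminate)
#' @export
hemolysis_check <- function(ct, samples, marker_stable = "miR-23a-3p",
                            marker_rbc = "miR-451a", threshold = 8) {
  for (m in c(marker_stable, marker_rbc)) {
    if (!m %in% target_ids(ct))
      stop(sprintf("hemolysis marker '%s' absent from the Cq matrix", m))
  }
  idx <- match(samples$sample_id, sample_ids(ct))
  if (anyNA(idx)) stop("sample table contains samples absent from the matrix")
  get_marker <- function(m) {
    v <- ct$values[m, idx]
    v[ct$status[m, idx] != "obs"] <- NA_real_
    v
  }
  d <- get_marker(marker_stable) - get_marker(marker_rbc)
  samples$hemolysis_delta_cq <- unname(d)
  samples$hemolysis_pass <- ifelse(is.na(d), NA, d < threshold)
  samples
}

#' Group-wise detection filter
#'
#' Keeps a target when its detection fraction is at least `min_frac`
#' (inclusive) in either of the two groups. The fraction is the number of
#' post-QC amplified wells over the number of samples in the group.
#'
#' @param ct a [ct_matrix()]
#' @param samples sample table covering the matrix columns
#' @param groups character pair of group labels (CNT/OMA/DIE or the derived
#'   union END)
#' @param min_frac detection threshold (default 0.75); `min_frac = 0` is the
#'   identity
#' @return the row-subsetted `ct_matrix`
#' @export
detection_filter <- function(ct, samples, groups = c("END", "CNT"),
                             min_frac = 0.75) {
  stopifnot(length(groups) == 2)
  samples <- samples[samples$sample_id %in% sample_ids(ct), , drop = FALSE]
  frac <- function(label) {
    ids <- samples$sample_id[group_mask(samples, label)]
    if (!length(ids)) stop(sprintf("group '%s' is empty", label))
    detected_fraction(ct, ids)
  }
  keep <- frac(groups[1]) >= min_frac | frac(groups[2]) >= min_frac
  ct[which(keep), ]
}
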