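#' Cq matrix with censoring status
#'
#' Container for an RT-qPCR panel: a targets x samples matrix of quantification
#' cycles (Cq) together with a per-well status and optional per-well quality
#' covariates. A well is one of:
#' \describe{
#'   \item{`"obs"`}{amplified; the Cq value is present and at most the
#'     detection limit.}
#'   \item{`"cens"`}{non-detect; the reaction never crossed threshold, so the
#'     true Cq is only known to exceed `detection_limit` (right-censored).}
#'   \item{`"excl"`}{removed by well-level QC; the measurement is a technical
#'     failure and carries no information about abundance.}
#' }
#' `values` is `NA` exactly where the status is not `"obs"`.
#'
#' @param values numeric matrix (targets x samples) with target ids as
#'   rownames and sample ids as colnames; `NA` for non-observed wells.
#' @param status character matrix of the same shape with entries
#'   `"obs"`, `"cens"`, `"excl"`; defaults to `"cens"` wherever `values` is
#'   `NA` and `"obs"` elsewhere.
#' @param detection_limit Cq detection limit (default 40); observed values must
#'   not exceed it.
#' @param amp_score,cq_confidence optional numeric matrices of per-well
#'   amplification score and Cq confidence (same shape as `values`).
#' @return an object of class `ct_matrix`.
#' @export
ct_matrix <- function(values, status = NULL, detection_limit = 40,
                      amp_score = NULL, cq_confidence = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (nrow(values) > 0 && is.null(rownames(values)))
    stop("'values' must carry target ids as rownames")
  if (ncol(values) > 0 && is.null(colnames(values)))
    stop("'values' must carry sample ids as colnames")
  if (is.null(rownames(values))) rownames(values) <- character(0)
  if (is.null(colnames(values))) colnames(values) <- character(0)
  if (anyDuplicated(rownames(values))) stop("duplicated target ids")
  if (anyDuplicated(colnames(values))) stop("duplicated sample ids")
  if (is.null(status)) {
    status <- ifelse(is.na(values), "cens", "obs")
    dimnames(status) <- dimnames(values)
  }
  if (!all(dim(status) == dim(values)))
    stop("'status' and 'values' dimensions disagree")
  if (!all(status %in% c("obs", "cens", "excl")))
    stop("'status' entries must be 'obs', 'cens' or 'excl'")
  if (any((status == "obs") != !is.na(values)))
    stop("values must be NA exactly where status is not 'obs'")
  obs <- values[status == "obs"]
  if (length(obs) && any(obs > detection_limit + 1e-9))
    stop("observed Cq values above the detection limit")
  chk <- function(m, what) {
    if (is.null(m)) return(NULL)
    if (!all(dim(m) == dim(values)))
      stop(sprintf("'%s' dimensions disagree with 'values'", what))
    dimnames(m) <- dimnames(values)
    m
  }
  structure(
    list(values = values, status = status,
         detection_limit = detection_limit,
         amp_score = chk(amp_score, "amp_score"),
         cq_confidence = chk(cq_confidence, "cq_confidence")),
    class = "ct_matrix")
}

#' @export
`[.ct_matrix` <- function(x, i, j) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  sub <- function(m) if (is.null(m)) NULL else m[i, j, drop = FALSE]
  ct_matrix(sub(x$values), sub(x$status), x$detection_limit,
            sub(x$amp_score), sub(x$cq_confidence))
}

#' @export
dim.ct_matrix <- function(x) dim(x$values)

#' @export
print.ct_matrix <- function(x, ...) {
  st <- table(factor(x$status, levels = c("obs", "cens", "excl")))
  cat(sprintf(
    "ct_matrix: %d targets x %d samples (limit Cq = %g)\n  wells: %d observed, %d censored, %d QC-excluded\n",
    nrow(x$values), ncol(x$values), x$detection_limit,
    st[["obs"]], st[["cens"]], st[["excl"]]))
  invisible(x)
}

#' Target and sample identifiers of a `ct_matrix`
#' @param ct a `ct_matrix`
#' @return character vector of ids
#' @export
target_ids <- function(ct) rownames(ct$values)

#' @rdname target_ids
#' @export
sample_ids <- function(ct) colnames(ct$values)

#' Per-target detection fraction
#'
#' Fraction of samples in which each target amplified (status `"obs"`), with
#' the full sample set as denominator: censored non-detects and QC-excluded
#' wells both count as undetected.
#'
#' @param ct a `ct_matrix`
#' @param sample_subset optional character vector of sample ids to restrict to
#' @return named numeric vector in `[0, 1]`
#' @export
detected_fraction <- function(ct, sample_subset = NULL) {
  st <- ct$status
  if (!is.null(sample_subset)) {
    miss <- setdiff(sample_subset, colnames(st))
    if (length(miss)) stop("unknown sample ids: ", paste(miss, collapse = ", "))
    st <- st[, sample_subset, drop = FALSE]
  }
  rowMeans(st == "obs")
}

# Logical mask over a sample table for a (possibly derived) group label.
# "END" is the union OMA+DIE, computed on demand and never stored.
group_mask <- function(samples, label) {
  if (label == "END") return(samples$group %in% c("OMA", "DIE"))
  if (!label %in% c("CNT", "OMA", "DIE"))
    stop(sprintf("unknown group label '%s' (expected CNT, OMA, DIE or END)", label))
  samples$group == label
}
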