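# Reading and writing the long-format Cq exchange format.
#
# cq table (TSV): sample_id, target_id, Cq (blank = non-detect), amp_score,
# cq_confidence. sample table (TSV): sample_id, group in {CNT, OMA, DIE}.
# Numeric fields are written with 17 significant digits so a write/read
# round trip reproduces doubles exactly.

fmt_num <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))

#' Write a Cq matrix and sample table as long-format TSV fixtures
#'
#' Emits one row per (sample, target) well. Wells that are not observed
#' (non-detects) get a blank Cq; QC covariates are written as-is. The files
#' are readable by [read_ct_long()] and the round trip reproduces `ct`
#' exactly for raw (pre-QC) matrices.
#'
#' @param ct a [ct_matrix()]
#' @param samples sample table (`sample_id`, `group`)
#' @param dir output directory (created if missing)
#' @return invisibly, the two file paths (`cq`, `samples`)
#' @export
write_fixture <- function(ct, samples, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  v <- ct$values
  long <- data.frame(
    sample_id = rep(colnames(v), each = nrow(v)),
    target_id = rep(rownames(v), times = ncol(v)),
    Cq = fmt_num(as.vector(v)),
    amp_score = fmt_num(if (is.null(ct$amp_score)) rep(NA_real_, length(v))
                        else as.vector(ct$amp_score)),
    cq_confidence = fmt_num(if (is.null(ct$cq_confidence))
                              rep(NA_real_, length(v))
                            else as.vector(ct$cq_confidence)),
    stringsAsFactors = FALSE)
  path_cq <- file.path(dir, "cq_long.tsv")
  path_samples <- file.path(dir, "samples.tsv")
  utils::write.table(long, path_cq, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(samples[, c("sample_id", "group")], path_samples,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(cq = path_cq, samples = path_samples))
}

#' Read long-format Cq and sample tables
#'
#' Builds a [ct_matrix()] (one cell per target x sample; blank Cq read as a
#' censored non-detect) and the sample table. Duplicate (target, sample) rows
#' are an error except for the designated replicate-control target (spotted
#' multiple times per array on OpenArray plates), whose wells are collapsed to
#' their mean with the per-sample replicate SD recorded in the sample table.
#'
#' @param path_cq path to the long-format Cq TSV
#' @param path_samples path to the sample TSV (`sample_id`, `group` with
#'   labels in CNT/OMA/DIE; "END" is a derived union, never a stored label)
#' @param detection_limit Cq detection limit (default 40)
#' @param replicate_target target id allowed to appear in replicate wells
#'   (default `"miR-16-5p"`)
#' @return list: `ct` (a `ct_matrix`), `samples` (data.frame with
#'   `mir16_replicate_sd` column, `NA` where no replicates were present)
#' @export
read_ct_long <- function(path_cq, path_samples, detection_limit = 40,
                         replicate_target = "miR-16-5p") {
  cq <- utils::read.delim(path_cq, sep = "\t", na.strings = "",
                          stringsAsFactors = FALSE,
                          colClasses = c(sample_id = "character",
                                         target_id = "character"))
  need <- c("sample_id", "target_id", "Cq")
  if (!all(need %in% names(cq)))
    stop("cq table must contain columns: ", paste(need, collapse = ", "))
  if (!"amp_score" %in% names(cq)) cq$amp_score <- NA_real_
  if (!"cq_confidence" %in% names(cq)) cq$cq_confidence <- NA_real_

  samples <- utils::read.delim(path_samples, sep = "\t", na.strings = "",
                               stringsAsFactors = FALSE,
                               colClasses = c(sample_id = "character"))
  if (!all(c("sample_id", "group") %in% names(samples)))
    stop("sample table must contain columns: sample_id, group")
  bad <- setdiff(unique(samples$group), c("CNT", "OMA", "DIE"))
  if (length(bad))
    stop("unknown group labels: ", paste(bad, collapse = ", "),
         " (END is the OMA+DIE union, derived not stored)")
  if (anyDuplicated(samples$sample_id)) stop("duplicated sample ids")
  unknown <- setdiff(unique(cq$sample_id), samples$sample_id)
  if (length(unknown))
    stop("cq table references samples absent from the sample table: ",
         paste(utils::head(unknown, 5), collapse = ", "))

  # replicate control: collapse multi-well targets, keep per-sample SD
  samples$mir16_replicate_sd <- NA_real_
  key <- paste(cq$target_id, cq$sample_id, sep = "\r")
  dup_keys <- unique(key[duplicated(key)])
  if (length(dup_keys)) {
    dup_targets <- unique(sub("\r.*", "", dup_keys))
    offenders <- setdiff(dup_targets, replicate_target)
    if (length(offenders))
      stop("duplicate (target, sample) rows for: ",
           paste(utils::head(offenders, 5), collapse = ", "))
    rep_rows <- cq$target_id == replicate_target
    rep_dat <- cq[rep_rows, ]
    agg_mean <- tapply(rep_dat$Cq, rep_dat$sample_id, mean, na.rm = TRUE)
    agg_sd <- tapply(rep_dat$Cq, rep_dat$sample_id,
                     function(x) stats::sd(x[!is.na(x)]))
    agg_amp <- tapply(rep_dat$amp_score, rep_dat$sample_id, mean, na.rm = TRUE)
    agg_conf <- tapply(rep_dat$cq_confidence, rep_dat$sample_id, mean,
                       na.rm = TRUE)
    collapsed <- data.frame(sample_id = names(agg_mean),
                            target_id = replicate_target,
                            Cq = ifelse(is.nan(agg_mean), NA_real_, agg_mean),
                            amp_score = ifelse(is.nan(agg_amp), NA_real_,
                                               agg_amp),
                            cq_confidence = ifelse(is.nan(agg_conf), NA_real_,
                                                   agg_conf),
                            stringsAsFactors = FALSE)
    cq <- rbind(cq[!rep_rows, ], collapsed)
    idx <- match(names(agg_sd), samples$sample_id)
    samples$mir16_replicate_sd[idx] <- as.numeric(agg_sd)
  }

  tids <- unique(cq$target_id)
  sids <- samples$sample_id
  v <- matrix(NA_real_, length(tids), length(sids),
              dimnames = list(tids, sids))
  amp <- v; conf <- v
  ij <- cbind(match(cq$target_id, tids), match(cq$sample_id, sids))
  v[ij] <- cq$Cq
  amp[ij] <- cq$amp_score
  conf[ij] <- cq$cq_confidence
  list(ct = ct_matrix(v, detection_limit = detection_limit,
                      amp_score = amp, cq_confidence = conf),
       samples = samples)
}

# Write a data.frame as TSV (helper for pipeline outputs).
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
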