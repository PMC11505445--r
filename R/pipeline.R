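# Pipeline orchestration: QC -> hemolysis screen -> reference selection ->
# differential expression -> optional enrichment, under one config and seed.

#' Run the full Cq analysis pipeline
#'
#' Stages, in order:
#' \enumerate{
#'   \item well-level QC ([apply_well_qc()]);
#'   \item hemolysis screen ([hemolysis_check()]); failing samples are
#'     excluded, indeterminate ones kept unless `drop_indeterminate`;
#'   \item detection filter for the END/CNT pair to form the reference
#'     candidate pool, censored imputation ([impute_censored()]), the four
#'     stability algorithms + TOST ([stability_table()]), and reference
#'     selection ([select_references()]); imputed values are then discarded;
#'   \item reference normalization of the un-imputed matrix and tobit
#'     differential expression for the four comparisons
#'     ([run_all_comparisons()]);
#'   \item if a target map and pathway collection are supplied,
#'     over-representation analysis of the targets of significant
#'     END-vs-CNT miRNAs ([ora_test()]); otherwise skipped with a notice.
#' }
#' Each stage that draws random numbers is seeded from `seed` plus a fixed
#' stage offset, so adding a stage never perturbs earlier draws and identical
#' (data, config, seed) give identical outputs.
#'
#' @param ct raw [ct_matrix()] with QC covariates
#' @param samples sample table (`sample_id`, `group`)
#' @param seed integer seed for the imputation stage
#' @param k_refs number of reference miRNAs (default 3)
#' @param alpha significance level (DE flag and TOST, default 0.05)
#' @param tost_margin TOST equivalence margin in Cq units (default 0.5, about
#'   a 1.4-fold bound)
#' @param min_amp_score,min_cq_conf,min_cq well QC thresholds
#' @param hemolysis_threshold delta Cq acceptance threshold (strict <, 8)
#' @param detection_min_frac group-wise detection threshold (0.75)
#' @param ref_min_detect reference detection screen (0.95)
#' @param comparisons list of `c(case, control)` pairs
#' @param target_map optional named list (miRNA -> genes) for enrichment
#' @param pathways optional named list of pathway gene sets
#' @param drop_indeterminate drop samples whose hemolysis status cannot be
#'   determined (default `FALSE`: keep with a flag)
#' @param outdir optional directory; when given, all result tables and a JSON
#'   run manifest are written there
#' @return list: `qc` (report), `samples` (annotated, analysis set flagged),
#'   `stability`, `references`, `de` (named list), `combined`, `enrichment`
#'   (or `NULL`), `manifest`
#' @export
run_pipeline <- function(ct, samples, seed = 1, k_refs = 3, alpha = 0.05,
                         tost_margin = 0.5, min_amp_score = 1,
                         min_cq_conf = 0.8, min_cq = 6,
                         hemolysis_threshold = 8, detection_min_frac = 0.75,
                         ref_min_detect = 0.95,
                         comparisons = list(c("END", "CNT"), c("OMA", "CNT"),
                                            c("DIE", "CNT"), c("DIE", "OMA")),
                         target_map = NULL, pathways = NULL,
                         drop_indeterminate = FALSE, outdir = NULL) {
  stopifnot(inherits(ct, "ct_matrix"))

  qc <- apply_well_qc(ct, min_amp_score, min_cq_conf, min_cq)
  ct_qc <- qc$ct
  samples <- hemolysis_check(ct_qc, samples, threshold = hemolysis_threshold)
  keep <- if (drop_indeterminate) isTRUE_vec(samples$hemolysis_pass)
          else is.na(samples$hemolysis_pass) | samples$hemolysis_pass
  samples$analysis_set <- keep
  n_hemo <- sum(!samples$hemolysis_pass, na.rm = TRUE)
  if (n_hemo) message(n_hemo, " hemolysed sample(s) excluded")
  ct_an <- ct_qc[, which(samples$analysis_set)]
  sam_an <- samples[samples$analysis_set, , drop = FALSE]

  # reference selection on the END/CNT candidate pool
  cand <- detection_filter(ct_an, sam_an, c("END", "CNT"),
                           min_frac = detection_min_frac)
  imp <- impute_censored(cand, sam_an, seed = seed + 1000L)
  grp <- ifelse(group_mask(sam_an, "END"), "END", "CNT")
  grp <- grp[match(colnames(imp$values), sam_an$sample_id)]
  # equivalence screen first: possibly-regulated targets must not enter the
  # stability pool (the model-based bias term assumes unregulated candidates)
  tost_p <- tost_screen(imp$values, grp, margin = tost_margin)
  pool <- names(tost_p)[tost_p < alpha]
  if (length(pool) < max(3, k_refs))
    stop(sprintf(paste0(
      "only %d candidate(s) are TOST-equivalent at margin %.2g: consider ",
      "relaxing the margin"), length(pool), tost_margin))
  stab <- stability_table(imp$values[pool, , drop = FALSE], grp,
                          tost_margin = NULL,
                          detected_frac = detected_fraction(cand))
  stab$tost_p <- unname(tost_p[stab$target_id])
  refset <- select_references(stab, cand, k = k_refs,
                              min_detect = ref_min_detect, alpha = alpha)

  # de-imputation is implicit: DE runs on the un-imputed post-QC matrix
  norm <- normalize_ct(ct_an, refset)
  de <- run_all_comparisons(norm, sam_an, comparisons = comparisons,
                            alpha = alpha, min_frac = detection_min_frac)
  combined <- combined_de_table(de)

  enrichment <- NULL
  if (!is.null(target_map) && !is.null(pathways)) {
    sig <- de[[1]]$target_id[de[[1]]$significant]
    mt <- map_targets(sig, target_map)
    if (length(mt$genes)) {
      universe <- sort(unique(unlist(target_map)))
      enrichment <- ora_test(mt$genes, pathways, universe)
    } else {
      warning("no target genes mapped for significant miRNAs; ",
              "enrichment skipped")
    }
  } else {
    message("no target map / pathway collection supplied: enrichment skipped")
  }

  manifest <- list(
    package = "mircq",
    version = as.character(utils::packageVersion("mircq")),
    seed = seed,
    thresholds = list(min_amp_score = min_amp_score,
                      min_cq_conf = min_cq_conf, min_cq = min_cq,
                      hemolysis_threshold = hemolysis_threshold,
                      detection_min_frac = detection_min_frac,
                      ref_min_detect = ref_min_detect, alpha = alpha,
                      tost_margin = tost_margin, k_refs = k_refs),
    comparisons = vapply(comparisons, paste, character(1), collapse = "_vs_"),
    n_targets = nrow(ct$values), n_samples = ncol(ct$values),
    wells_removed_by_qc = qc$n_removed,
    hemolysed_excluded = n_hemo,
    n_candidates = nrow(cand$values),
    stability_excluded = imp$excluded,
    reference_ids = refset$reference_ids)

  res <- list(qc = list(n_removed = qc$n_removed), samples = samples,
              stability = stab, references = refset, de = de,
              combined = combined, enrichment = enrichment,
              manifest = manifest)
  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  res
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Write pipeline result tables and manifest
#'
#' @param res a [run_pipeline()] result
#' @param outdir output directory (created if missing)
#' @return invisibly, the output directory
#' @export
write_pipeline_outputs <- function(res, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  write_tsv(res$samples, file.path(outdir, "qc_samples.tsv"))
  write_tsv(res$stability, file.path(outdir, "stability.tsv"))
  write_tsv(data.frame(target_id = res$references$reference_ids),
            file.path(outdir, "references.tsv"))
  nf <- res$references$norm_factor
  write_tsv(data.frame(sample_id = names(nf), norm_factor = nf),
            file.path(outdir, "norm_factor.tsv"))
  for (nm in names(res$de))
    write_tsv(res$de[[nm]], file.path(outdir, paste0("de_", nm, ".tsv")))
  write_tsv(res$combined, file.path(outdir, "de_combined.tsv"))
  if (!is.null(res$enrichment))
    write_tsv(res$enrichment, file.path(outdir, "enrichment.tsv"))
  jsonlite::write_json(res$manifest,
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}
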