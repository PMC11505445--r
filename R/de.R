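# Reference normalization and censored-regression differential expression.

#' Reference-normalize a Cq matrix
#'
#' Subtracts the per-sample normalization factor from every Cq
#' (delta Ct = Cq - factor) and propagates the censoring limit per sample as
#' `detection_limit - factor`. Reference miRNAs are removed from the matrix
#' (they are not tested); samples with an `NA` factor are dropped with a
#' warning. The missingness pattern is exactly the post-QC pattern: imputed
#' values never enter differential expression.
#'
#' @param ct the post-QC [ct_matrix()]
#' @param refset a `reference_set` from [select_references()], or a list with
#'   `reference_ids` and `norm_factor`
#' @return list of class `norm_matrix`: `delta` (targets x samples), `status`,
#'   `censor_limits` (per-sample), `detection_limit`
#' @export
normalize_ct <- function(ct, refset) {
  nf <- refset$norm_factor
  stopifnot(!is.null(nf), !is.null(names(nf)))
  nf <- nf[sample_ids(ct)]
  keep_s <- which(is.finite(nf))
  if (length(keep_s) < ncol(ct$values))
    warning(ncol(ct$values) - length(keep_s),
            " sample(s) without a normalization factor dropped")
  keep_t <- setdiff(target_ids(ct), refset$reference_ids)
  delta <- sweep(ct$values[keep_t, keep_s, drop = FALSE], 2, nf[keep_s])
  structure(list(delta = delta,
                 status = ct$status[keep_t, keep_s, drop = FALSE],
                 censor_limits = ct$detection_limit - nf[keep_s],
                 detection_limit = ct$detection_limit),
            class = "norm_matrix")
}

#' Censored-regression differential expression for one comparison
#'
#' For each target passing the group-wise detection filter, fits the
#' two-group tobit model on the normalized delta Ct with per-sample censoring
#' limits (case coded 1), so `beta1` is the delta-delta Ct and the fold
#' change is `2^(-beta1)`. QC-excluded wells contribute nothing. Per-target
#' fit failures are reported as rows with `NA` statistics, never dropped.
#' Results carry Benjamini-Hochberg q-values and are sorted by fold change,
#' descending.
#'
#' @param norm a [normalize_ct()] result
#' @param samples sample table (covering at least the normalized samples)
#' @param case,control group labels (CNT/OMA/DIE or the derived END)
#' @param alpha significance level for the `significant` flag (default 0.05)
#' @param min_frac group-wise detection threshold applied for this pair
#'   (default 0.75)
#' @return data.frame, one row per tested target
#' @export
compare_groups <- function(norm, samples, case, control, alpha = 0.05,
                           min_frac = 0.75) {
  samples <- samples[match(colnames(norm$delta), samples$sample_id), ,
                     drop = FALSE]
  in_case <- group_mask(samples, case)
  in_ctrl <- group_mask(samples, control)
  if (any(in_case & in_ctrl))
    stop(sprintf("groups '%s' and '%s' overlap", case, control))
  if (!any(in_case) || !any(in_ctrl)) stop("empty comparison group")
  use <- in_case | in_ctrl
  st <- norm$status[, use, drop = FALSE]
  dl <- norm$delta[, use, drop = FALSE]
  lim <- norm$censor_limits[use]
  g <- as.numeric(in_case[use])

  det_case <- rowMeans(st[, g == 1, drop = FALSE] == "obs")
  det_ctrl <- rowMeans(st[, g == 0, drop = FALSE] == "obs")
  keep <- det_case >= min_frac | det_ctrl >= min_frac
  tids <- rownames(dl)[keep]

  rows <- lapply(tids, function(t) {
    s <- st[t, ]
    inc <- s != "excl"
    y <- dl[t, inc]
    cens <- s[inc] == "cens"
    fit <- tryCatch(
      tobit_two_group(y, cens, g[inc], lim[inc]),
      error = function(e) NULL)
    base <- data.frame(
      target_id = t,
      n_obs_case = sum(s == "obs" & g == 1),
      n_cens_case = sum(s == "cens" & g == 1),
      n_obs_ctrl = sum(s == "obs" & g == 0),
      n_cens_ctrl = sum(s == "cens" & g == 0),
      stringsAsFactors = FALSE)
    if (is.null(fit)) {
      base$delta_delta_ct <- NA_real_; base$fold_change <- NA_real_
      base$se <- NA_real_; base$p_value <- NA_real_
      base$converged <- FALSE
    } else {
      base$delta_delta_ct <- fit$beta1
      base$fold_change <- 2^(-fit$beta1)
      base$se <- fit$se_beta1
      base$p_value <- fit$p_value
      base$converged <- fit$converged
    }
    base
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(res)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- !is.na(res$p_value) & res$p_value < alpha
  res[order(-res$fold_change), , drop = FALSE]
}

#' Run the four standard group comparisons
#'
#' END vs CNT, OMA vs CNT, DIE vs CNT, DIE vs OMA (END being the OMA+DIE
#' union, derived at comparison time). Detection filtering is applied per
#' comparison pair.
#'
#' @param norm a [normalize_ct()] result
#' @param samples sample table
#' @param comparisons list of `c(case, control)` pairs
#' @inheritParams compare_groups
#' @return named list of [compare_groups()] tables (`"END_vs_CNT"` etc.)
#' @export
run_all_comparisons <- function(norm, samples,
                                comparisons = list(c("END", "CNT"),
                                                   c("OMA", "CNT"),
                                                   c("DIE", "CNT"),
                                                   c("DIE", "OMA")),
                                alpha = 0.05, min_frac = 0.75) {
  out <- lapply(comparisons, function(cc)
    compare_groups(norm, samples, cc[1], cc[2], alpha = alpha,
                   min_frac = min_frac))
  names(out) <- vapply(comparisons, function(cc)
    paste0(cc[1], "_vs_", cc[2]), character(1))
  out
}

#' Combined wide differential-expression table
#'
#' One row per target appearing in any comparison, with fold change and
#' p-value side by side per comparison; cells with p >= `p_mask` (or untested
#' targets) are masked as `"-"`, mirroring the usual reporting convention for
#' these panels.
#'
#' @param de_list named list of [compare_groups()] tables
#' @param p_mask masking threshold (default 0.1)
#' @return character data.frame with `target_id` and `FC_*` / `p_*` columns
#' @export
combined_de_table <- function(de_list, p_mask = 0.1) {
  shown <- lapply(de_list, function(d)
    d[!is.na(d$p_value) & d$p_value < p_mask, , drop = FALSE])
  tids <- unique(unlist(lapply(shown, function(d) d$target_id)))
  # order by the best (largest) displayed fold change across comparisons
  best_fc <- vapply(tids, function(t) {
    fcs <- unlist(lapply(shown, function(d) d$fold_change[d$target_id == t]))
    if (!length(fcs)) -Inf else max(fcs)
  }, numeric(1))
  tids <- tids[order(-best_fc)]
  out <- data.frame(target_id = tids, stringsAsFactors = FALSE)
  for (nm in names(de_list)) {
    d <- shown[[nm]]
    i <- match(tids, d$target_id)
    out[[paste0("FC_", nm)]] <- ifelse(is.na(i), "-",
                                       sprintf("%.3f", d$fold_change[i]))
    out[[paste0("p_", nm)]] <- ifelse(is.na(i), "-",
                                      sprintf("%.4f", d$p_value[i]))
  }
  out
}
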