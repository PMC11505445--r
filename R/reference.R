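# Reference-miRNA selection: censored imputation, four stability algorithms
# (geNorm, comparative delta-Ct, BestKeeper, NormFinder), consensus rank
# aggregation, TOST equivalence screening and the per-sample normalization
# factor.

#' Impute non-detects from group-wise censored-normal fits
#'
#' For each target, the mean and SD are estimated per group (END = OMA+DIE
#' versus CNT, so that imputation cannot manufacture spurious homogeneity
#' between the arms) with [fit_censored_normal()], counting non-detects as
#' right-censored at the detection limit. Each censored cell is then filled
#' with a draw from the fitted normal truncated to `[limit, Inf)`; each
#' QC-excluded cell (a technical dropout, uninformative about abundance) is
#' filled with a draw from the fitted untruncated normal. Observed cells are
#' never modified. Targets with fewer than 2 amplified wells in either group
#' are excluded.
#'
#' The completed matrix exists only to feed the stability algorithms;
#' downstream differential expression always goes back to the un-imputed
#' data.
#'
#' @param ct a [ct_matrix()] (post QC, analysis samples only)
#' @param samples sample table for the matrix columns
#' @param seed optional integer seed for the imputation draws
#' @return list: `values` (complete numeric matrix, excluded targets
#'   dropped), `excluded` (character vector of dropped target ids),
#'   `fits` (per-target list of per-group `censored_fit`s)
#' @export
impute_censored <- function(ct, samples, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  samples <- samples[match(sample_ids(ct), samples$sample_id), , drop = FALSE]
  grp_cols <- list(END = which(group_mask(samples, "END")),
                   CNT = which(group_mask(samples, "CNT")))
  out <- ct$values
  L <- ct$detection_limit
  excluded <- character(0)
  fits <- list()
  for (i in seq_len(nrow(out))) {
    tid <- rownames(out)[i]
    fit_g <- list()
    ok <- TRUE
    for (g in names(grp_cols)) {
      cols <- grp_cols[[g]]
      st <- ct$status[i, cols]
      v <- ct$values[i, cols]
      obs <- v[st == "obs"]
      n_cens <- sum(st == "cens")
      if (length(obs) < 2) { ok <- FALSE; break }
      fit <- tryCatch(
        fit_censored_normal(c(obs, rep(NA_real_, n_cens)),
                            c(rep(FALSE, length(obs)), rep(TRUE, n_cens)), L),
        error = function(e) NULL)
      if (is.null(fit)) { ok <- FALSE; break }
      fit_g[[g]] <- fit
    }
    if (!ok) { excluded <- c(excluded, tid); next }
    for (g in names(grp_cols)) {
      cols <- grp_cols[[g]]
      st <- ct$status[i, cols]
      fit <- fit_g[[g]]
      i_cens <- cols[st == "cens"]
      if (length(i_cens))
        out[i, i_cens] <- sample_truncated_normal(length(i_cens), fit$mu,
                                                  fit$sigma, L)
      i_excl <- cols[st == "excl"]
      if (length(i_excl))
        out[i, i_excl] <- stats::rnorm(length(i_excl), fit$mu, fit$sigma)
    }
    fits[[tid]] <- fit_g
  }
  keep <- setdiff(rownames(out), excluded)
  if (length(excluded))
    message(length(excluded),
            " target(s) excluded from stability analysis (fewer than 2 ",
            "amplified wells in a group or non-identifiable fit)")
  list(values = out[keep, , drop = FALSE], excluded = excluded, fits = fits)
}

# mean over j != i of SD_samples(x_i - x_j), computed from the sample
# covariance matrix: Var(x_i - x_j) = V_ii + V_jj - 2 V_ij.
pairwise_sd_mean <- function(mat) {
  V <- stats::cov(t(mat))
  v <- diag(V)
  S2 <- outer(v, v, "+") - 2 * V
  S2[S2 < 0] <- 0  # guard rounding for perfectly co-varying pairs
  S <- sqrt(S2)
  diag(S) <- 0
  rowSums(S) / (nrow(mat) - 1)
}

#' geNorm stability (M) with iterative worst-gene exclusion
#'
#' The geNorm measure for candidate i is the mean, over all other candidates
#' j, of the across-sample SD of the pairwise difference Cq_i - Cq_j (the
#' log-ratio of abundances). The classic algorithm then repeatedly removes
#' the least stable gene (largest M) and recomputes, until two genes remain;
#' the ranking is the reverse elimination order with the final pair tied at
#' rank 1.5. `genorm_m` is the first-pass M over the full candidate set.
#'
#' @param mat complete numeric matrix, candidates x samples (>= 3 rows)
#' @return data.frame: `target_id`, `genorm_m`, `genorm_rank`
#' @export
genorm_m <- function(mat) {
  k <- nrow(mat)
  if (k < 3) stop("geNorm requires at least 3 candidates")
  if (ncol(mat) < 2) stop("geNorm requires at least 2 samples")
  m_first <- pairwise_sd_mean(mat)
  active <- seq_len(k)
  elim <- integer(0)
  while (length(active) > 2) {
    m <- pairwise_sd_mean(mat[active, , drop = FALSE])
    worst <- active[which.max(m)]
    elim <- c(elim, worst)
    active <- setdiff(active, worst)
  }
  rk <- numeric(k)
  rk[active] <- 1.5
  if (length(elim)) rk[elim] <- seq(k, 3)  # first out = least stable
  data.frame(target_id = rownames(mat), genorm_m = unname(m_first),
             genorm_rank = rk, stringsAsFactors = FALSE)
}

#' Comparative delta-Ct stability
#'
#' Single-pass mean pairwise-difference SD: identical to the first geNorm
#' iteration, but with no elimination; candidates are ranked ascending by the
#' score (average ranks on ties).
#'
#' @param mat complete numeric matrix, candidates x samples (>= 2 rows)
#' @return data.frame: `target_id`, `deltact_score`, `deltact_rank`
#' @export
comparative_deltact <- function(mat) {
  if (nrow(mat) < 2) stop("comparative delta-Ct requires at least 2 candidates")
  s <- pairwise_sd_mean(mat)
  data.frame(target_id = rownames(mat), deltact_score = unname(s),
             deltact_rank = rank(s, ties.method = "average"),
             stringsAsFactors = FALSE)
}

#' BestKeeper descriptive stability statistics
#'
#' Per candidate: the across-sample Cq SD (n-1 denominator), the coefficient
#' of variation CV = 100 * SD / mean, and the Pearson correlation with the
#' BestKeeper index (the per-sample arithmetic mean Cq over all candidates).
#' Candidates are ranked ascending by SD, BestKeeper's primary criterion; a
#' zero-variance candidate has undefined correlation, set to 1 by convention.
#'
#' @param mat complete numeric matrix, candidates x samples (>= 2 columns)
#' @return data.frame: `target_id`, `bestkeeper_sd`, `bestkeeper_cv`,
#'   `bestkeeper_r`, `bestkeeper_rank`
#' @export
bestkeeper_stats <- function(mat) {
  if (ncol(mat) < 2) stop("BestKeeper requires at least 2 samples")
  sds <- apply(mat, 1, stats::sd)
  means <- rowMeans(mat)
  idx <- colMeans(mat)
  r <- rep(1, nrow(mat))
  nz <- sds > 0 & stats::sd(idx) > 0
  if (any(nz)) r[nz] <- apply(mat[nz, , drop = FALSE], 1, stats::cor, y = idx)
  if (any(!nz)) message(sum(!nz), " zero-variance candidate(s): BestKeeper r set to 1")
  data.frame(target_id = rownames(mat), bestkeeper_sd = unname(sds),
             bestkeeper_cv = unname(100 * sds / means),
             bestkeeper_r = unname(r),
             bestkeeper_rank = rank(sds, ties.method = "average"),
             stringsAsFactors = FALSE)
}

#' NormFinder model-based stability
#'
#' Variance-decomposition stability on the Cq (log) scale, following the
#' model of Andersen et al. (2004). Within each group the matrix is two-way
#' centered (gene and sample effects removed); the per-gene residual variance
#' is bias-corrected for the contamination introduced by estimating the
#' sample effect from k genes: with t_ig the raw residual mean square,
#' sigma2_ig = (t_ig - mean_i(t_ig) * k / (k-1) / k) / (1 - 2/k). The
#' inter-group bias d_ig (gene-by-group interaction of the group means) is
#' shrunk toward zero by its sampling variance,
#' d~ = d * gamma2 / (gamma2 + sigma2/n_g), with gamma2 the method-of-moments
#' estimate of the true bias variance. The stability value is
#' mean_g |d~_ig| + mean_g sqrt(sigma2_ig / n_g); lower is more stable.
#' With a single group the inter-group term is dropped.
#'
#' @param mat complete numeric matrix, candidates x samples (>= 3 rows)
#' @param groups group label per column (two or more levels, each with >= 3
#'   samples; a single level triggers the intra-group fallback)
#' @return data.frame: `target_id`, `normfinder_stability`, `normfinder_rank`
#' @export
normfinder_stability <- function(mat, groups) {
  k <- nrow(mat)
  if (k < 3) stop("NormFinder requires at least 3 candidates")
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(mat))
  glev <- unique(groups)
  n_g <- table(factor(groups, levels = glev))
  if (any(n_g < 3)) stop("each group needs at least 3 samples")
  G <- length(glev)

  sig2 <- matrix(NA_real_, k, G)
  gmean <- matrix(NA_real_, k, G)
  for (gi in seq_len(G)) {
    sub <- mat[, groups == glev[gi], drop = FALSE]
    n <- ncol(sub)
    res <- sub - rowMeans(sub) -
      matrix(colMeans(sub), k, n, byrow = TRUE) + mean(sub)
    t_ig <- rowSums(res^2) / (n - 1)
    sbar2 <- mean(t_ig) * k / (k - 1)        # unbiased mean variance
    s2 <- (t_ig - sbar2 / k) / (1 - 2 / k)   # per-gene bias correction
    sig2[, gi] <- pmax(s2, 1e-12)
    gmean[, gi] <- rowMeans(sub)
  }

  if (G == 1) {
    message("single group: NormFinder reduces to the intra-group variance term")
    stab <- sqrt(sig2[, 1] / as.numeric(n_g[1]))
  } else {
    # gene-by-group interaction of the group means (unweighted centering)
    d <- gmean - rowMeans(gmean) -
      matrix(colMeans(gmean), k, G, byrow = TRUE) + mean(gmean)
    var_d <- sweep(sig2, 2, as.numeric(n_g), "/")
    # method-of-moments estimate of the true bias variance; the centered
    # interactions carry (k-1)(G-1) degrees of freedom
    gamma2 <- max(0, sum(d^2) / ((k - 1) * (G - 1)) - mean(var_d))
    d_shrunk <- d * gamma2 / (gamma2 + var_d)
    stab <- rowMeans(abs(d_shrunk)) + rowMeans(sqrt(var_d))
  }
  data.frame(target_id = rownames(mat), normfinder_stability = unname(stab),
             normfinder_rank = rank(stab, ties.method = "average"),
             stringsAsFactors = FALSE)
}

#' Consensus rank aggregation over stability algorithms
#'
#' The overall score of a candidate is the geometric mean of its per-algorithm
#' ranks (RefFinder-style); lower means more stable, and the score is
#' invariant to the order of the algorithm columns.
#'
#' @param ranks numeric matrix or data.frame of per-algorithm ranks, one row
#'   per candidate (no missing entries)
#' @return numeric vector of geometric-mean rank scores
#' @export
aggregate_ranks <- function(ranks) {
  m <- as.matrix(ranks)
  if (anyNA(m)) stop("missing ranks: exclude the candidate before aggregating")
  if (any(m < 1)) stop("ranks must be >= 1")
  exp(rowMeans(log(m)))
}

#' TOST equivalence screen over a complete matrix
#'
#' Per-target TOST p-value between two arms (Welch-based, see
#' [tost_two_group()]), computed row-wise on a complete (imputed) matrix.
#' Used to drop possibly-regulated targets before stability estimation:
#' NormFinder's inter-group bias term assumes the candidate pool is
#' unregulated, so regulated targets must not contaminate it.
#'
#' @param mat complete numeric matrix (targets x samples)
#' @param groups two-level group label per column
#' @param margin equivalence margin in Cq units
#' @return named vector of TOST p-values
#' @export
tost_screen <- function(mat, groups, margin = 0.5) {
  glev <- unique(as.character(groups))
  stopifnot(length(glev) == 2)
  a <- groups == glev[1]
  p <- apply(mat, 1, function(v)
    tost_two_group(v[a], v[!a], margin = margin)$p_tost)
  stats::setNames(p, rownames(mat))
}

#' Full stability table over a complete candidate matrix
#'
#' Runs the four stability algorithms and aggregates their ranks; optionally
#' attaches the per-candidate TOST equivalence p-value between the two groups
#' (computed on the same complete matrix) and the detection fraction from the
#' un-imputed data.
#'
#' @param mat complete numeric matrix (candidates x samples), e.g. from
#'   [impute_censored()]
#' @param groups two-level group label per column (END/CNT)
#' @param tost_margin equivalence margin in Cq units; `NULL` skips TOST
#' @param detected_frac optional named vector of detection fractions
#' @return data.frame, one row per candidate, sorted by `overall_rank_score`
#' @export
stability_table <- function(mat, groups, tost_margin = 0.5,
                            detected_frac = NULL) {
  gn <- genorm_m(mat)
  dc <- comparative_deltact(mat)
  bk <- bestkeeper_stats(mat)
  nf <- normfinder_stability(mat, groups)
  tab <- Reduce(function(a, b) merge(a, b, by = "target_id", sort = FALSE),
                list(gn, dc, bk, nf))
  tab$overall_rank_score <- aggregate_ranks(
    tab[, c("genorm_rank", "deltact_rank", "bestkeeper_rank",
            "normfinder_rank")])
  if (!is.null(tost_margin))
    tab$tost_p <- unname(tost_screen(mat, groups,
                                     margin = tost_margin)[tab$target_id])
  if (!is.null(detected_frac))
    tab$detected_frac <- unname(detected_frac[tab$target_id])
  tab[order(tab$overall_rank_score, tab$genorm_m), , drop = FALSE]
}

#' Select the reference miRNA set and per-sample normalization factor
#'
#' Candidates must be detected in at least `min_detect` of the samples
#' (inclusive) and TOST-equivalent between the arms at level `alpha`; among
#' those, the `k` best by consensus rank (ties broken by geNorm M) become the
#' reference set. The per-sample normalization factor is the arithmetic mean
#' of the observed reference Cq values; a sample missing any reference after
#' QC gets an `NA` factor and a warning (it is dropped at normalization).
#' The imputed values used for stability scoring play no further role.
#'
#' @param stab stability table from [stability_table()] with `tost_p` and
#'   `detected_frac` columns
#' @param ct the un-imputed post-QC [ct_matrix()] (for the factor)
#' @param k number of references (default 3)
#' @param min_detect detection-fraction screen (default 0.95)
#' @param alpha TOST equivalence level (default 0.05)
#' @return list of class `reference_set`: `reference_ids`, `norm_factor`
#'   (named per-sample vector), `candidates` (the screened stability table)
#' @export
select_references <- function(stab, ct, k = 3, min_detect = 0.95,
                              alpha = 0.05) {
  if (!all(c("tost_p", "detected_frac") %in% names(stab)))
    stop("stability table must carry 'tost_p' and 'detected_frac' columns")
  pool <- stab[stab$detected_frac >= min_detect & stab$tost_p < alpha, ,
               drop = FALSE]
  if (nrow(pool) < k)
    stop(sprintf(paste0(
      "only %d candidate(s) pass the screens (need %d): consider relaxing ",
      "the TOST margin or the %.0f%% detection threshold"),
      nrow(pool), k, 100 * min_detect))
  pool <- pool[order(pool$overall_rank_score, pool$genorm_m), , drop = FALSE]
  refs <- pool$target_id[seq_len(k)]
  nf <- reference_norm_factor(ct, refs)
  structure(list(reference_ids = refs, norm_factor = nf, candidates = pool),
            class = "reference_set")
}

#' Per-sample normalization factor from a reference set
#'
#' Arithmetic mean of the observed reference Cq values per sample. Samples
#' in which any reference did not amplify (post-QC) get `NA` with a warning.
#'
#' @param ct a [ct_matrix()]
#' @param reference_ids reference target ids (must be rows of `ct`)
#' @return named numeric vector over the samples of `ct`
#' @export
reference_norm_factor <- function(ct, reference_ids) {
  miss <- setdiff(reference_ids, target_ids(ct))
  if (length(miss)) stop("references absent from matrix: ",
                         paste(miss, collapse = ", "))
  v <- ct$values[reference_ids, , drop = FALSE]
  v[ct$status[reference_ids, , drop = FALSE] != "obs"] <- NA_real_
  nf <- colMeans(v)
  if (anyNA(nf))
    warning(sum(is.na(nf)), " sample(s) missing a reference after QC; ",
            "their normalization factor is NA and they are dropped at ",
            "normalization")
  nf
}
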