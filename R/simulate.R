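# Synthetic serum miRNA cohort generator.
#
# Emulates an OpenArray-style 754-target serum panel on two clinical arms:
# endometriosis (END = OMA endometrioma + DIE deep-infiltrating subgroups) and
# controls (CNT). Each miRNA's Cq is normal on the log2-abundance (Cq) scale
# with a per-sample loading offset shared across targets (RNA input
# variability, the reason reference normalization exists); draws above the
# detection limit are non-detects, i.e. right-censored. A minority of targets
# is expressed at detectable levels, matching the sparsity of serum profiles;
# stable reference miRNAs, group effects and hemolysed samples are planted and
# recorded in a ground-truth table.

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the study design this package models: 754 targets, 60
#' controls and 67 endometriosis samples (40 OMA + 27 DIE), detection limit
#' Cq = 40, and roughly 130 targets detectable in at least 75% of either
#' group's samples.
#'
#' @param n_targets panel size (default 754)
#' @param n_cnt,n_oma,n_die samples per clinical group (defaults 60, 40, 27)
#' @param detection_limit Cq above which a reaction is a non-detect (40)
#' @param n_expressed number of targets expressed at serum-detectable levels;
#'   the remainder get baseline means from `mu_bg_range` and essentially never
#'   pass detection filtering
#' @param mu_range baseline mean Cq interval for expressed targets
#' @param mu_bg_range baseline mean Cq interval for unexpressed targets
#'   (at or beyond the detection limit)
#' @param sigma_range per-target biological + technical SD interval (Cq units)
#' @param n_refs number of planted stable reference miRNAs (group-invariant
#'   mean, SD drawn from `ref_sigma_range`)
#' @param ref_sigma_range SD interval for planted references
#' @param n_de number of planted differentially expressed miRNAs; each gets
#'   the same Cq shift in both OMA and DIE (an END-level effect), so the
#'   DIE-vs-OMA contrast is null by construction
#' @param effect_range interval of |delta Ct| for planted effects; signs are
#'   random. Effect sign convention: effect = mean Cq(case) - mean Cq(control),
#'   so a negative effect means higher abundance in cases (fold change > 1).
#' @param sample_effect_sd SD of the per-sample global Cq offset (residual
#'   RNA loading variability after input equalization; default 0.5 Cq)
#' @param frac_hemolysed proportion of samples with simulated hemolysis
#'   (miR-451a excess; delta Cq(miR-23a-3p - miR-451a) >= 8 by construction)
#' @param qc_fail_rate proportion of amplified wells carrying failing QC
#'   covariates (amplification score <= 1 and Cq confidence <= 0.8)
#' @param markers include the hemolysis marker pair miR-23a-3p / miR-451a as
#'   the first two targets (required when `frac_hemolysed > 0`)
#' @param seed integer seed; `simulate_cohort` is bit-reproducible given it
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_targets = 754, n_cnt = 60, n_oma = 40, n_die = 27,
                       detection_limit = 40, n_expressed = 130,
                       mu_range = c(22, 34), mu_bg_range = c(40, 46),
                       sigma_range = c(0.5, 2.5),
                       n_refs = 3, ref_sigma_range = c(0.15, 0.35),
                       n_de = 20, effect_range = c(0.5, 4),
                       sample_effect_sd = 0.5,
                       frac_hemolysed = 0.03, qc_fail_rate = 0.02,
                       markers = TRUE, seed = NULL) {
  cfg <- list(n_targets = n_targets, n_cnt = n_cnt, n_oma = n_oma,
              n_die = n_die, detection_limit = detection_limit,
              n_expressed = n_expressed, mu_range = mu_range,
              mu_bg_range = mu_bg_range, sigma_range = sigma_range,
              n_refs = n_refs, ref_sigma_range = ref_sigma_range,
              n_de = n_de, effect_range = effect_range,
              sample_effect_sd = sample_effect_sd,
              frac_hemolysed = frac_hemolysed, qc_fail_rate = qc_fail_rate,
              markers = markers, seed = seed)
  with(cfg, {
    if (any(c(n_cnt, n_oma, n_die) <= 0)) stop("sample counts must be positive")
    if (n_targets < 1) stop("n_targets must be positive")
    if (n_refs < 0 || n_de < 0) stop("counts must be non-negative")
    if (n_refs + n_de > n_targets)
      stop("n_refs + n_de exceeds n_targets")
    if (n_expressed > n_targets) stop("n_expressed exceeds n_targets")
    n_special <- n_refs + n_de + if (markers) 2L else 0L
    if (n_special > n_expressed)
      stop("planted references, DE targets and markers exceed n_expressed")
    if (frac_hemolysed < 0 || frac_hemolysed > 1 ||
        qc_fail_rate < 0 || qc_fail_rate > 1)
      stop("proportions must lie in [0, 1]")
    if (frac_hemolysed > 0 && !markers)
      stop("hemolysis simulation requires the marker pair (markers = TRUE)")
    if (diff(mu_range) < 0 || diff(sigma_range) < 0 || diff(effect_range) < 0)
      stop("ranges must be non-decreasing intervals")
    if (any(sigma_range <= 0)) stop("sigma_range must be positive")
  })
  structure(cfg, class = "sim_config")
}

#' Simulate a synthetic Cq cohort with planted ground truth
#'
#' Draws a full panel under the generative model of [sim_config()]: per-target
#' normal Cq with group-dependent means, per-sample loading offsets, right
#' censoring at the detection limit, planted stable references, planted group
#' effects, QC-failing wells and hemolysed samples.
#'
#' @param config a [sim_config()]
#' @return list with elements
#'   \describe{
#'     \item{ct}{a [ct_matrix()] (QC covariates attached; QC-failing wells
#'       still carry their Cq until [apply_well_qc()] is run)}
#'     \item{samples}{data.frame with `sample_id`, `group`}
#'     \item{truth}{list: `reference_ids`, `de_effects` (data.frame
#'       `target_id`, `comparison`, `effect`; zero rows when `n_de = 0`),
#'       `hemolysed_ids`, plus the per-target `mu` and `sigma` used}
#'   }
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  if (!is.null(cf$seed)) set.seed(cf$seed)

  n_samp <- cf$n_cnt + cf$n_oma + cf$n_die
  samples <- data.frame(
    sample_id = c(sprintf("CNT_%03d", seq_len(cf$n_cnt)),
                  sprintf("OMA_%03d", seq_len(cf$n_oma)),
                  sprintf("DIE_%03d", seq_len(cf$n_die))),
    group = rep(c("CNT", "OMA", "DIE"), c(cf$n_cnt, cf$n_oma, cf$n_die)),
    stringsAsFactors = FALSE)

  n_marker <- if (cf$markers) 2L else 0L
  tids <- sprintf("miR-sim-%04d", seq_len(cf$n_targets - n_marker))
  if (cf$markers) tids <- c("miR-23a-3p", "miR-451a", tids)

  expressed <- seq_len(cf$n_expressed)  # markers, if present, are expressed
  mu <- numeric(cf$n_targets)
  sigma <- stats::runif(cf$n_targets, cf$sigma_range[1], cf$sigma_range[2])
  mu[expressed] <- stats::runif(length(expressed), cf$mu_range[1], cf$mu_range[2])
  bg <- setdiff(seq_len(cf$n_targets), expressed)
  mu[bg] <- stats::runif(length(bg), cf$mu_bg_range[1], cf$mu_bg_range[2])
  if (cf$markers) {
    mu[1] <- 26; sigma[1] <- 0.6   # miR-23a-3p, hemolysis-insensitive
    mu[2] <- 21; sigma[2] <- 0.6   # miR-451a, red-blood-cell miRNA
  }

  resample <- function(x, k) x[sample.int(length(x), k)]  # safe for length-1 x
  plantable <- setdiff(expressed, seq_len(n_marker))
  ref_idx <- sort(resample(plantable, cf$n_refs))
  if (cf$n_refs) {
    sigma[ref_idx] <- stats::runif(cf$n_refs, cf$ref_sigma_range[1],
                                   cf$ref_sigma_range[2])
  }
  de_idx <- sort(resample(setdiff(plantable, ref_idx), cf$n_de))
  effect <- numeric(cf$n_targets)
  if (cf$n_de) {
    effect[de_idx] <- stats::runif(cf$n_de, cf$effect_range[1],
                                   cf$effect_range[2]) *
      sample(c(-1, 1), cf$n_de, replace = TRUE)
  }

  is_case <- samples$group %in% c("OMA", "DIE")
  sample_offset <- stats::rnorm(n_samp, 0, cf$sample_effect_sd)
  mu_mat <- matrix(mu, cf$n_targets, n_samp) +
    outer(effect, as.numeric(is_case)) +
    matrix(sample_offset, cf$n_targets, n_samp, byrow = TRUE)
  vals <- mu_mat + matrix(stats::rnorm(cf$n_targets * n_samp), cf$n_targets) *
    sigma
  dimnames(vals) <- list(tids, samples$sample_id)

  hemolysed <- samples$sample_id[stats::runif(n_samp) < cf$frac_hemolysed]
  if (length(hemolysed)) {
    j <- match(hemolysed, samples$sample_id)
    # red-blood-cell miR-451a in large excess: delta Cq (23a - 451a) >= 8
    vals["miR-451a", j] <- vals["miR-23a-3p", j] - 8 -
      stats::runif(length(j), 0.5, 3)
  }

  status <- ifelse(vals > cf$detection_limit, "cens", "obs")
  vals[status == "cens"] <- NA_real_

  amp <- matrix(NA_real_, cf$n_targets, n_samp)
  conf <- matrix(NA_real_, cf$n_targets, n_samp)
  n_obs <- sum(status == "obs")
  fail <- status == "obs" & matrix(stats::runif(cf$n_targets * n_samp),
                                   cf$n_targets) < cf$qc_fail_rate
  pass <- status == "obs" & !fail
  amp[pass] <- stats::runif(sum(pass), 1.2, 2.0)
  conf[pass] <- stats::runif(sum(pass), 0.85, 1.0)
  amp[fail] <- stats::runif(sum(fail), 0.2, 1.0)
  conf[fail] <- stats::runif(sum(fail), 0.4, 0.8)

  de_effects <- data.frame(target_id = character(0), comparison = character(0),
                           effect = numeric(0), stringsAsFactors = FALSE)
  if (cf$n_de) {
    de_effects <- data.frame(
      target_id = rep(tids[de_idx], times = 3),
      comparison = rep(c("END_vs_CNT", "OMA_vs_CNT", "DIE_vs_CNT"),
                       each = cf$n_de),
      effect = rep(effect[de_idx], times = 3),
      stringsAsFactors = FALSE)
  }

  list(ct = ct_matrix(vals, status, cf$detection_limit, amp, conf),
       samples = samples,
       truth = list(reference_ids = tids[ref_idx],
                    de_effects = de_effects,
                    hemolysed_ids = hemolysed,
                    mu = stats::setNames(mu, tids),
                    sigma = stats::setNames(sigma, tids)))
}

#' Synthetic miRNA-target annotation and pathway collection
#'
#' Builds a validated-interaction style miRNA-to-gene map over a synthetic
#' gene universe, plus GMT-style pathway gene sets, with one pathway planted
#' to be over-represented among the targets of a chosen miRNA set. Used to
#' exercise the over-representation stage without external databases; all ids
#' are synthetic.
#'
#' @param target_ids miRNA ids to annotate
#' @param planted_ids miRNA ids whose target genes seed the planted pathway
#' @param n_genes size of the synthetic gene universe
#' @param genes_per_mirna interval for per-miRNA target-set sizes
#' @param n_pathways number of background pathways
#' @param pathway_size interval for pathway sizes
#' @param seed optional integer seed
#' @return list: `target_map` (named list of gene vectors), `pathways`
#'   (named list of gene vectors), `planted_pathway` (its name, or `NULL`)
#' @export
simulate_annotation <- function(target_ids, planted_ids = character(0),
                                n_genes = 2000, genes_per_mirna = c(5, 40),
                                n_pathways = 30, pathway_size = c(20, 150),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  target_map <- lapply(target_ids, function(t) {
    k <- sample(genes_per_mirna[1]:genes_per_mirna[2], 1)
    sort(sample(genes, k))
  })
  names(target_map) <- target_ids
  pathways <- lapply(seq_len(n_pathways), function(i) {
    k <- sample(pathway_size[1]:pathway_size[2], 1)
    sort(sample(genes, k))
  })
  names(pathways) <- sprintf("PATH%03d", seq_len(n_pathways))
  planted <- NULL
  planted_ids <- intersect(planted_ids, target_ids)
  if (length(planted_ids)) {
    seed_genes <- unique(unlist(target_map[planted_ids]))
    k <- min(length(seed_genes), pathway_size[2])
    extra <- sample(setdiff(genes, seed_genes), pathway_size[1])
    pathways[["PATH_PLANTED"]] <- sort(unique(c(
      sample(seed_genes, k), extra)))
    planted <- "PATH_PLANTED"
  }
  list(target_map = target_map, pathways = pathways, planted_pathway = planted)
}
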