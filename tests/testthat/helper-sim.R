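# Small cohorts and toy matrices shared across tests.

small_config <- function(seed = 1, ...) {
  args <- list(n_targets = 60, n_expressed = 24, n_cnt = 14, n_oma = 8,
               n_die = 7, n_refs = 2, n_de = 4, effect_range = c(1.5, 3),
               frac_hemolysed = 0, qc_fail_rate = 0.02, seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# tiny ct_matrix straight from a values matrix (QC covariates all passing)
toy_ct <- function(values, limit = 40) {
  amp <- matrix(1.5, nrow(values), ncol(values))
  conf <- matrix(0.95, nrow(values), ncol(values))
  amp[is.na(values)] <- NA; conf[is.na(values)] <- NA
  ct_matrix(values, detection_limit = limit, amp_score = amp,
            cq_confidence = conf)
}

toy_samples <- function(ct) {
  ids <- sample_ids(ct)
  data.frame(sample_id = ids,
             group = ifelse(grepl("^C", ids), "CNT",
                            ifelse(grepl("^O", ids), "OMA", "DIE")),
             stringsAsFactors = FALSE)
}

named_matrix <- function(data, nrow, tprefix = "t", sprefix = "C") {
  m <- matrix(data, nrow = nrow)
  dimnames(m) <- list(paste0(tprefix, seq_len(nrow)),
                      paste0(sprefix, seq_len(ncol(m))))
  m
}
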