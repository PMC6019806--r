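# Shared fixture builders (all fixtures are generated in code).

make_pheno <- function(n = 40, seed = 1) {
  set.seed(seed)
  phenotype_table(data.frame(
    sample_id = sprintf("S%02d", seq_len(n)),
    er_status = sample(c("ERpos", "ERneg"), n, replace = TRUE),
    subtype = sample(c("Luminal", "BasalA", "BasalB"), n, replace = TRUE),
    stringsAsFactors = FALSE
  ))
}

# hand-built pair-fit rows for gene-summary tests
make_fits <- function(gene, beta1, beta1_p, status = "ok") {
  k <- length(beta1)
  data.frame(
    gene = rep(gene, k),
    probeset_id = sprintf("%s_ps%d", gene, seq_len(k)),
    probe_id = sprintf("%s_pr%d", gene, seq_len(k)),
    beta0 = 7, beta1 = beta1, beta2_ERpos = 0, beta3_BasalA = 0,
    beta3_BasalB = 0, beta1_se = 0.1, beta1_p = beta1_p,
    residual_df = 35L, n_used = 40L,
    status = rep_len(status, k),
    stringsAsFactors = FALSE
  )
}

# probe state vector from (hyper, hypo, na) counts
states_from_counts <- function(n_hyper, n_hypo, n_na) {
  c(rep("hyper", n_hyper), rep("hypo", n_hypo), rep(NA_character_, n_na))
}

# small synthetic edge-list file
write_edge_file <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
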