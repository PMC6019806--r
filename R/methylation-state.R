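#' One-sample t-test hyper/hypomethylation call for a probe
#'
#' Tests whether a probe's mean M-value across samples differs from zero
#' (two-sided one-sample t-test). A probe is hypermethylated when the mean
#' M-value is positive and `p < alpha`, hypomethylated when the mean is
#' negative and `p < alpha`, and `NA` otherwise. Probes with fewer than two
#' non-missing values or zero variance cannot be tested and are reported as
#' `NA` with `degenerate = TRUE`.
#'
#' @param m_values numeric vector of M-values across samples.
#' @param alpha significance threshold.
#' @return one-row data.frame with columns `mean_meth`, `t_stat`, `p`,
#'   `state` (`"hyper"`, `"hypo"` or `NA`), `degenerate`.
#' @export
probe_t_test <- function(m_values, alpha = 0.05) {
  v <- m_values[is.finite(m_values)]
  mean_meth <- if (length(v)) mean(v) else NA_real_
  if (length(v) < 2L || stats::var(v) == 0) {
    .msg("probe_t_test: degenerate probe (n=%d, zero variance or too few values)",
         length(v))
    return(data.frame(mean_meth = mean_meth, t_stat = NA_real_, p = NA_real_,
                      state = NA_character_, degenerate = TRUE,
                      stringsAsFactors = FALSE))
  }
  tt <- stats::t.test(v, mu = 0)
  p <- tt$p.value
  state <- if (mean_meth > 0 && p < alpha) "hyper"
    else if (mean_meth < 0 && p < alpha) "hypo" else NA_character_
  data.frame(mean_meth = mean_meth, t_stat = unname(tt$statistic), p = p,
             state = state, degenerate = FALSE, stringsAsFactors = FALSE)
}

#' Hyper/hypomethylation states for the probes of selected genes
#'
#' @param meth methylation [omics_matrix()] (probes x samples).
#' @param annotation a [gene_annotation()].
#' @param genes genes to test; default all annotated genes.
#' @param alpha significance threshold for [probe_t_test()].
#' @return data.frame with one row per probe: `probe_id`, `gene`,
#'   `mean_meth`, `t_stat`, `p`, `state`, `degenerate`.
#' @export
probe_states <- function(meth, annotation, genes = NULL, alpha = 0.05) {
  ann <- annotation[annotation$feature_kind == "probe", ]
  if (!is.null(genes)) ann <- ann[ann$gene %in% genes, ]
  ann <- ann[order(ann$gene, ann$feature_id), ]
  missing <- setdiff(ann$feature_id, rownames(meth))
  if (length(missing))
    .err("probe(s) absent from the methylation matrix: %s",
         paste(utils::head(missing, 5L), collapse = ", "))
  rows <- lapply(seq_len(nrow(ann)), function(i)
    cbind(data.frame(probe_id = ann$feature_id[i], gene = ann$gene[i],
                     stringsAsFactors = FALSE),
          probe_t_test(meth[ann$feature_id[i], ], alpha)))
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(probe_id = character(), gene = character(),
                      mean_meth = numeric(), t_stat = numeric(), p = numeric(),
                      state = character(), degenerate = logical(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Summarize probe methylation states for one gene
#'
#' Counts hyper-, hypo- and untyped (`NA`) probes and converts them to
#' percentages rounded half-up to two decimals, the rendering used in
#' per-gene probe-state tables (e.g. 11/16 hyper -> 68.75%).
#'
#' @param states probe states of a single gene: a data.frame with a `state`
#'   column (see [probe_states()]) or a character vector of states.
#' @return one-row data.frame: `gene` (if available), `n_hyper`, `n_hypo`,
#'   `n_na`, `pct_hyper`, `pct_hypo`, `pct_na`.
#' @export
summarize_gene_meth <- function(states) {
  gene <- NA_character_
  if (is.data.frame(states)) {
    if ("gene" %in% names(states) && nrow(states))
      gene <- unique(states$gene)
    if (length(gene) > 1L) .err("states must belong to a single gene")
    states <- states$state
  }
  total <- length(states)
  if (total == 0L) .err("no probe states to summarize")
  n_hyper <- sum(states == "hyper", na.rm = TRUE)
  n_hypo <- sum(states == "hypo", na.rm = TRUE)
  n_na <- total - n_hyper - n_hypo
  data.frame(gene = gene,
             n_hyper = n_hyper, n_hypo = n_hypo, n_na = n_na,
             pct_hyper = round_half_up(100 * n_hyper / total, 2),
             pct_hypo = round_half_up(100 * n_hypo / total, 2),
             pct_na = round_half_up(100 * n_na / total, 2),
             stringsAsFactors = FALSE)
}

#' Per-gene methylation-state summaries
#'
#' @param states output of [probe_states()] (possibly several genes).
#' @return data.frame with one [summarize_gene_meth()] row per gene.
#' @export
summarize_meth_by_gene <- function(states) {
  out <- do.call(rbind, lapply(split(states, states$gene), summarize_gene_meth))
  rownames(out) <- NULL
  out[order(out$gene), , drop = FALSE]
}

#' Is a gene's probe panel majority-hypermethylated?
#'
#' TRUE when the gene has strictly more hypermethylated probes than
#' hypomethylated and untyped probes combined.
#'
#' @param summary one-row output of [summarize_gene_meth()] (or a list with
#'   `n_hyper`, `n_hypo`, `n_na`).
#' @return logical.
#' @export
is_majority_hyper <- function(summary) {
  summary$n_hyper > summary$n_hypo + summary$n_na
}

#' Flag probesets expressed below the housekeeping level
#'
#' Housekeeping genes sit at or above log2 expression 8 on this scale; a
#' probeset whose maximum expression across all samples stays strictly
#' below the threshold is flagged as low-expressed.
#'
#' @param expr expression [omics_matrix()].
#' @param genes genes of interest.
#' @param annotation a [gene_annotation()].
#' @param housekeeping_threshold reference expression level (default 8).
#' @return data.frame with one row per (gene, probeset): `gene`,
#'   `probeset_id`, `max_expr`, `below_housekeeping`.
#' @export
flag_low_expression <- function(expr, genes, annotation,
                                housekeeping_threshold = 8) {
  ann <- annotation[annotation$feature_kind == "probeset" &
                      annotation$gene %in% genes, ]
  skipped <- setdiff(genes, ann$gene)
  if (length(skipped))
    .msg("flag_low_expression: %d gene(s) without probesets skipped: %s",
         length(skipped), paste(utils::head(skipped, 5L), collapse = ", "))
  ann <- ann[order(ann$gene, ann$feature_id), ]
  missing <- setdiff(ann$feature_id, rownames(expr))
  if (length(missing))
    .err("probeset(s) absent from the expression matrix: %s",
         paste(utils::head(missing, 5L), collapse = ", "))
  mx <- apply(expr[ann$feature_id, , drop = FALSE], 1L, max, na.rm = TRUE)
  data.frame(gene = ann$gene, probeset_id = ann$feature_id,
             max_expr = unname(mx),
             below_housekeeping = unname(mx < housekeeping_threshold),
             stringsAsFactors = FALSE)
}
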