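#' Classify a gene as long or short
#'
#' Genes vary widely in how many probesets and probes map to them; applying
#' one significance rule to all of them would penalize genes with many
#' pairs. A gene is "long" when it has more than `probeset_cut` probesets or
#' more than `probe_cut` probes (strict inequalities); otherwise "short".
#' The default cuts (2 probesets, 20 probes) sit near the third quartiles of
#' typical array annotations.
#'
#' @param m,n integer vectors: probesets and probes per gene.
#' @param probeset_cut,probe_cut strict thresholds.
#' @return character vector in \{"long", "short"\}.
#' @export
classify_gene_length <- function(m, n, probeset_cut = 2, probe_cut = 20) {
  if (any(m < 1L) || any(n < 1L)) .err("m and n must be >= 1")
  ifelse(m > probeset_cut | n > probe_cut, "long", "short")
}

.summarize_one <- function(fits, m, n, alpha, long_frac, short_frac,
                           probeset_cut, probe_cut) {
  ok <- fits$status == "ok"
  n_pairs <- sum(ok)
  n_sig <- sum(ok & !is.na(fits$beta1_p) & fits$beta1_p < alpha)
  n_pos <- sum(ok & fits$beta1 > 0)
  n_neg <- sum(ok & fits$beta1 < 0)
  frac_sig <- if (n_pairs > 0L) n_sig / n_pairs else NA_real_
  length_class <- classify_gene_length(m, n, probeset_cut, probe_cut)
  cutoff <- if (length_class == "long") long_frac else short_frac
  direction <- if (n_pairs > 0L && n_pos > n_pairs / 2) "positive"
    else if (n_pairs > 0L && n_neg > n_pairs / 2) "negative" else "none"
  list(length_class = length_class, m = as.integer(m), n = as.integer(n),
       n_pairs = as.integer(n_pairs), n_sig_pairs = as.integer(n_sig),
       frac_sig = frac_sig,
       n_pos_coeff = as.integer(n_pos), n_neg_coeff = as.integer(n_neg),
       direction = direction,
       passes_frac_threshold = n_pairs > 0L && frac_sig > cutoff,
       flagged = n_pairs == 0L)
}

#' Summarize the pair fits of one gene
#'
#' Counts significant pairs (`beta1_p < alpha`) and coefficient signs over
#' the gene's non-degenerate pair fits, applies the length-class fraction
#' rule (strictly more than `long_frac` of pairs significant for long
#' genes, `short_frac` for short genes) and calls the gene's direction:
#' positive/negative when strictly more than half of the pairs have a
#' positive/negative methylation coefficient, otherwise none. Degenerate
#' fits are excluded from both numerator and denominator; a gene with only
#' degenerate fits is reported with `n_pairs = 0`, direction none, and
#' `flagged = TRUE`.
#'
#' @param fits pair-fit rows of a single gene (see [fit_all_pairs()]).
#' @param m,n annotation counts of the gene's probesets and probes.
#' @param alpha pair-level significance threshold.
#' @param long_frac,short_frac strict significant-fraction thresholds.
#' @param probeset_cut,probe_cut length-class cuts, see
#'   [classify_gene_length()].
#' @return one-row data.frame (gene-level summary).
#' @export
summarize_gene <- function(fits, m, n, alpha = 0.05, long_frac = 0.15,
                           short_frac = 0.30, probeset_cut = 2,
                           probe_cut = 20) {
  if (length(unique(fits$gene)) > 1L) .err("fits must belong to a single gene")
  out <- .summarize_one(fits, m, n, alpha, long_frac, short_frac,
                        probeset_cut, probe_cut)
  cbind(data.frame(gene = if (nrow(fits)) fits$gene[1L] else NA_character_,
                   stringsAsFactors = FALSE),
        as.data.frame(out, stringsAsFactors = FALSE))
}

#' Summarize all genes of an annotation
#'
#' Applies [summarize_gene()] to every gene in the annotation, including
#' genes that contributed no usable pairs (reported with `n_pairs = 0` and
#' flagged), so the output covers the same gene set as the annotation.
#'
#' @param fits pair-fit table from [fit_all_pairs()].
#' @param annotation a [gene_annotation()].
#' @inheritParams summarize_gene
#' @return data.frame with one row per annotated gene.
#' @export
summarize_genes <- function(fits, annotation, alpha = 0.05, long_frac = 0.15,
                            short_frac = 0.30, probeset_cut = 2,
                            probe_cut = 20) {
  sizes <- annotation_sizes(annotation)
  by_gene <- split(seq_len(nrow(fits)), factor(fits$gene, levels = sizes$gene))
  rows <- lapply(seq_len(nrow(sizes)), function(i) {
    f <- fits[by_gene[[sizes$gene[i]]], , drop = FALSE]
    .summarize_one(f, sizes$m[i], sizes$n[i], alpha, long_frac, short_frac,
                   probeset_cut, probe_cut)
  })
  out <- cbind(data.frame(gene = sizes$gene, stringsAsFactors = FALSE),
               do.call(rbind, lapply(rows, as.data.frame,
                                     stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Filter pairs by methylation-coefficient magnitude and significance
#'
#' Selects pairs with a large methylation coefficient in the requested
#' direction (`beta1 > coeff_cut` for `"pos"`, `beta1 < -coeff_cut` for
#' `"neg"`) that are also significant (`beta1_p < alpha`), and reports the
#' qualifying pair count and the unique genes among them. Because one gene
#' may contribute several pairs, the gene count never exceeds the pair
#' count.
#'
#' @param fits pair-fit table from [fit_all_pairs()].
#' @param coeff_cut positive coefficient magnitude threshold (strict).
#' @param sign `"pos"` or `"neg"`.
#' @param alpha pair-level significance threshold.
#' @return list with `threshold_label` (e.g. `"gt0.5"`, `"ltm0.5"`),
#'   `n_pairs`, and sorted `genes`.
#' @export
coeff_filter <- function(fits, coeff_cut, sign = c("pos", "neg"),
                         alpha = 0.05) {
  sign <- match.arg(sign)
  if (coeff_cut < 0) .err("coeff_cut must be non-negative")
  ok <- fits$status == "ok" & !is.na(fits$beta1_p)
  qual <- if (sign == "pos") ok & fits$beta1 > coeff_cut
          else ok & fits$beta1 < -coeff_cut
  qual <- qual & fits$beta1_p < alpha
  lab <- paste0(if (sign == "pos") "gt" else "ltm", format(coeff_cut))
  list(threshold_label = lab,
       n_pairs = sum(qual),
       genes = sort(unique(fits$gene[qual])))
}

#' Merge the long-gene and short-gene significant lists
#'
#' The long and short significant lists partition by length class, so the
#' merge is a disjoint union; an overlap indicates an upstream error and is
#' rejected.
#'
#' @param long_set,short_set character vectors of gene symbols.
#' @return sorted union of the two sets.
#' @export
merge_long_short <- function(long_set, short_set) {
  overlap <- intersect(long_set, short_set)
  if (length(overlap))
    .err("long and short gene lists overlap (%s): a gene has exactly one length class",
         paste(utils::head(overlap, 5L), collapse = ", "))
  sort(union(long_set, short_set))
}

#' Intersect a coefficient-filtered gene list with a summary-based list
#'
#' The final gene lists require both a large, significant methylation
#' coefficient in at least one pair and a sufficient fraction of
#' significant pairs at the gene level; this is their intersection.
#'
#' @param coeff_genes,summary_genes character vectors of gene symbols.
#' @return sorted intersection.
#' @export
intersect_final <- function(coeff_genes, summary_genes) {
  sort(intersect(coeff_genes, summary_genes))
}

#' Build all significant-gene lists
#'
#' Runs the full gene-list pipeline over gene summaries and pair fits:
#' long/short positive/negative lists from the fraction rule and direction
#' call, their merges, the coefficient-magnitude filters at each cut, and
#' the final intersections
#' (`pos_final = gt-cut genes `intersect` pos_merged`, mirrored for the
#' negative side). Also emits audit tables of pair and gene counts per
#' coefficient filter and of list sizes.
#'
#' @param summaries output of [summarize_genes()].
#' @param fits output of [fit_all_pairs()].
#' @param alpha pair-level significance threshold.
#' @param coeff_cuts numeric vector of coefficient cuts; the first is used
#'   for the final intersections.
#' @return list of class `significant_gene_lists` with the nine gene sets
#'   (`pos_long`, `pos_short`, `neg_long`, `neg_short`, `pos_merged`,
#'   `neg_merged`, `pos_final`, `neg_final`, `all_final`), the per-filter
#'   results (`filters`), and audit tables `filter_table` and `list_table`.
#' @export
build_lists <- function(summaries, fits, alpha = 0.05,
                        coeff_cuts = c(0.5, 1)) {
  if (!all(fits$gene %in% summaries$gene))
    .err("fits contain genes absent from the summaries")
  pick <- function(class, dir) {
    sel <- summaries$length_class == class &
      summaries$passes_frac_threshold & summaries$direction == dir
    sort(summaries$gene[sel])
  }
  pos_long <- pick("long", "positive"); pos_short <- pick("short", "positive")
  neg_long <- pick("long", "negative"); neg_short <- pick("short", "negative")
  pos_merged <- merge_long_short(pos_long, pos_short)
  neg_merged <- merge_long_short(neg_long, neg_short)

  filters <- list()
  for (cut in coeff_cuts) {
    fp <- coeff_filter(fits, cut, "pos", alpha)
    fn <- coeff_filter(fits, cut, "neg", alpha)
    filters[[fp$threshold_label]] <- fp
    filters[[fn$threshold_label]] <- fn
  }
  first_pos <- paste0("gt", format(coeff_cuts[1L]))
  first_neg <- paste0("ltm", format(coeff_cuts[1L]))
  pos_final <- intersect_final(filters[[first_pos]]$genes, pos_merged)
  neg_final <- intersect_final(filters[[first_neg]]$genes, neg_merged)
  all_final <- sort(union(pos_final, neg_final))

  filter_table <- data.frame(
    threshold_label = vapply(filters, `[[`, character(1L), "threshold_label"),
    n_pairs = vapply(filters, `[[`, integer(1L), "n_pairs"),
    n_genes = vapply(filters, function(f) length(f$genes), integer(1L)),
    stringsAsFactors = FALSE
  )
  rownames(filter_table) <- NULL
  list_table <- data.frame(
    list = c("pos_long", "pos_short", "neg_long", "neg_short", "pos_merged",
             "neg_merged", "pos_final", "neg_final", "all_final"),
    n_genes = c(length(pos_long), length(pos_short), length(neg_long),
                length(neg_short), length(pos_merged), length(neg_merged),
                length(pos_final), length(neg_final), length(all_final)),
    stringsAsFactors = FALSE
  )
  structure(list(
    pos_long = pos_long, pos_short = pos_short,
    neg_long = neg_long, neg_short = neg_short,
    pos_merged = pos_merged, neg_merged = neg_merged,
    pos_final = pos_final, neg_final = neg_final, all_final = all_final,
    filters = filters, filter_table = filter_table, list_table = list_table
  ), class = "significant_gene_lists")
}
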