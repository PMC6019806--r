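#' Construct and validate an omics matrix
#'
#' An omics matrix is a plain numeric matrix with unique feature IDs as row
#' names and unique sample IDs as column names. One matrix holds expression
#' (probesets x samples, RMA-style log abundance, typically in \[2, 13.5\]),
#' another methylation (probes x samples, M-values = log2(R/G), typically in
#' \[-4, 4\]). Missing values are allowed.
#'
#' @param values numeric matrix (features x samples).
#' @param feature_ids,sample_ids character vectors of unique IDs; default to
#'   the dimnames of `values`.
#' @return a validated numeric matrix with dimnames set.
#' @export
omics_matrix <- function(values, feature_ids = rownames(values),
                         sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    .err("values must be a numeric matrix")
  if (is.null(feature_ids) || is.null(sample_ids))
    .err("feature_ids and sample_ids are required (as arguments or dimnames)")
  if (length(feature_ids) != nrow(values))
    .err("feature_ids length (%d) does not match number of rows (%d)",
         length(feature_ids), nrow(values))
  if (length(sample_ids) != ncol(values))
    .err("sample_ids length (%d) does not match number of columns (%d)",
         length(sample_ids), ncol(values))
  if (anyDuplicated(feature_ids))
    .err("duplicate feature IDs: %s",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    .err("duplicate sample IDs: %s",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  dimnames(values) <- list(feature_ids, sample_ids)
  values
}

.sep_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a feature-by-sample matrix from delimited text
#'
#' The file must have a header row of sample IDs and a first column of
#' feature IDs. TSV is the default dialect; `.csv` files are parsed as CSV.
#' Non-numeric cells (including the literal `NA` and empty cells) become
#' missing values.
#'
#' @param path path to a TSV/CSV file.
#' @param orientation only `"features_as_rows"` is supported.
#' @return an [omics_matrix()] (features x samples).
#' @export
read_matrix <- function(path, orientation = "features_as_rows") {
  orientation <- match.arg(orientation, "features_as_rows")
  if (!file.exists(path)) .err("file not found: %s", path)
  sep <- .sep_for(path)
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(raw)]
  if (length(raw) < 2L) .err("malformed matrix file (need header + data): %s", path)
  fields <- strsplit(raw, sep, fixed = TRUE)
  header <- fields[[1L]]
  body <- fields[-1L]
  widths <- lengths(body)
  expected <- widths[1L]
  bad <- which(widths != expected)
  if (length(bad))
    .err("ragged row at line %d of %s (%d fields, expected %d)",
         bad[1L] + 1L, path, widths[bad[1L]], expected)
  # header may or may not carry a corner cell above the feature-ID column
  if (expected == length(header) + 1L) {
    samples <- header
  } else if (expected == length(header)) {
    samples <- header[-1L]
  } else {
    .err("malformed header in %s: %d header fields for rows of %d fields",
         path, length(header), expected)
  }
  ids <- vapply(body, `[[`, character(1L), 1L)
  vals <- do.call(rbind, lapply(body, function(r)
    suppressWarnings(as.numeric(r[-1L]))))
  omics_matrix(vals, feature_ids = ids, sample_ids = samples)
}

#' Write an omics matrix as delimited text
#'
#' Values are written with 17 significant digits so a write/read round trip
#' reproduces doubles exactly.
#'
#' @param mat an [omics_matrix()].
#' @param path output path; `.csv` extension selects CSV, otherwise TSV.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(mat, path) {
  sep <- .sep_for(path)
  chr <- matrix(vapply(mat, function(v)
    if (is.na(v)) "NA" else sprintf("%.17g", v), character(1L)),
    nrow = nrow(mat))
  lines <- c(
    paste(c("feature_id", colnames(mat)), collapse = sep),
    vapply(seq_len(nrow(mat)), function(i)
      paste(c(rownames(mat)[i], chr[i, ]), collapse = sep), character(1L))
  )
  writeLines(lines, path)
  invisible(path)
}

.ER_SYNONYMS <- c(
  "ERpos" = "ERpos", "ER+" = "ERpos", "ER +" = "ERpos", "pos" = "ERpos",
  "positive" = "ERpos",
  "ERneg" = "ERneg", "ER-" = "ERneg", "ER−" = "ERneg", "neg" = "ERneg",
  "negative" = "ERneg"
)
.SUBTYPE_SYNONYMS <- c(
  "Luminal" = "Luminal", "luminal" = "Luminal",
  "BasalA" = "BasalA", "Basal A" = "BasalA", "basalA" = "BasalA",
  "BasalB" = "BasalB", "Basal B" = "BasalB", "basalB" = "BasalB"
)

#' Validate a phenotype table
#'
#' One row per sample with `er_status` in \{ERpos, ERneg\} and `subtype` in
#' \{Luminal, BasalA, BasalB\}. Common synonyms ("ER+", "Basal B", ...) are
#' normalized.
#'
#' @param df data.frame with columns `sample_id`, `er_status`, `subtype`.
#' @return the normalized data.frame.
#' @export
phenotype_table <- function(df) {
  need <- c("sample_id", "er_status", "subtype")
  miss <- setdiff(need, names(df))
  if (length(miss)) .err("phenotype table missing column(s): %s",
                         paste(miss, collapse = ", "))
  df <- df[, need]
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    .err("duplicate sample IDs in phenotype table: %s",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  er_in <- trimws(as.character(df$er_status))
  er <- unname(.ER_SYNONYMS[er_in])
  if (anyNA(er))
    .err("unknown er_status value(s): %s (allowed: ERpos, ERneg and synonyms ER+, ER-)",
         paste(unique(er_in[is.na(er)]), collapse = ", "))
  sub_in <- trimws(as.character(df$subtype))
  sub <- unname(.SUBTYPE_SYNONYMS[sub_in])
  if (anyNA(sub))
    .err("unknown subtype value(s): %s (allowed: Luminal, BasalA, BasalB)",
         paste(unique(sub_in[is.na(sub)]), collapse = ", "))
  df$er_status <- er
  df$subtype <- sub
  rownames(df) <- NULL
  df
}

#' Read a phenotype table from delimited text
#'
#' @param path TSV/CSV file with columns `sample_id`, `er_status`, `subtype`.
#' @return a normalized phenotype data.frame (see [phenotype_table()]).
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) .err("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = .sep_for(path),
                          quote = "", comment.char = "",
                          colClasses = "character", check.names = FALSE)
  phenotype_table(df)
}

#' Validate a gene annotation
#'
#' A long-format table mapping genes to their expression probesets and
#' methylation probes. Within one annotation a probeset or probe may belong
#' to at most one gene. Genes lacking either kind of feature are dropped
#' with a warning (no probeset-probe pairs can be formed for them).
#'
#' @param df data.frame with columns `gene`, `feature_id`, `feature_kind`
#'   (`"probeset"` or `"probe"`).
#' @return the validated data.frame (possibly with genes dropped).
#' @export
gene_annotation <- function(df) {
  need <- c("gene", "feature_id", "feature_kind")
  miss <- setdiff(need, names(df))
  if (length(miss)) .err("annotation missing column(s): %s",
                         paste(miss, collapse = ", "))
  df <- df[, need]
  for (cn in need) df[[cn]] <- as.character(df[[cn]])
  if (nrow(df) == 0L) return(df)
  bad_kind <- setdiff(unique(df$feature_kind), c("probeset", "probe"))
  if (length(bad_kind))
    .err("unknown feature_kind value(s): %s (allowed: probeset, probe)",
         paste(bad_kind, collapse = ", "))
  df <- unique(df)
  for (kind in c("probeset", "probe")) {
    sub <- df[df$feature_kind == kind, ]
    multi <- unique(sub$feature_id[duplicated(sub$feature_id)])
    if (length(multi))
      .err("%s(s) mapped to more than one gene: %s", kind,
           paste(multi, collapse = ", "))
  }
  has_ps <- unique(df$gene[df$feature_kind == "probeset"])
  has_pr <- unique(df$gene[df$feature_kind == "probe"])
  keep <- intersect(has_ps, has_pr)
  dropped <- setdiff(unique(df$gene), keep)
  if (length(dropped)) {
    warning(sprintf("dropping %d gene(s) without both probesets and probes: %s",
                    length(dropped), paste(dropped, collapse = ", ")),
            call. = FALSE)
    df <- df[df$gene %in% keep, ]
  }
  df <- df[order(df$gene, df$feature_kind, df$feature_id), ]
  rownames(df) <- NULL
  df
}

#' Read a gene annotation from delimited text
#'
#' Accepts either one long-format file (columns `gene`, `feature_id`,
#' `feature_kind`) or two two-column files (`gene`, `feature_id`), the first
#' listing probesets and the second listing probes.
#'
#' @param path long-format annotation file, or the gene-probeset file when
#'   `probes_path` is given.
#' @param probes_path optional gene-probe file.
#' @return a validated long-format annotation data.frame.
#' @export
read_annotation <- function(path, probes_path = NULL) {
  read_two_col <- function(p, kind) {
    df <- utils::read.table(p, header = TRUE, sep = .sep_for(p), quote = "",
                            comment.char = "", colClasses = "character",
                            check.names = FALSE)
    if (ncol(df) < 2L) .err("annotation file %s needs columns gene, feature_id", p)
    data.frame(gene = df[[1L]], feature_id = df[[2L]], feature_kind = kind,
               stringsAsFactors = FALSE)
  }
  if (!file.exists(path)) .err("file not found: %s", path)
  if (is.null(probes_path)) {
    first <- readLines(path, n = 1L, warn = FALSE)
    if (length(first) == 0L)
      return(gene_annotation(data.frame(gene = character(), feature_id = character(),
                                        feature_kind = character())))
    df <- utils::read.table(path, header = TRUE, sep = .sep_for(path), quote = "",
                            comment.char = "", colClasses = "character",
                            check.names = FALSE)
    gene_annotation(df)
  } else {
    gene_annotation(rbind(read_two_col(path, "probeset"),
                          read_two_col(probes_path, "probe")))
  }
}

#' Per-gene probeset and probe counts
#'
#' @param annotation a [gene_annotation()] data.frame.
#' @return data.frame with columns `gene`, `m` (probesets), `n` (probes).
#' @export
annotation_sizes <- function(annotation) {
  if (nrow(annotation) == 0L)
    return(data.frame(gene = character(), m = integer(), n = integer()))
  tab <- table(annotation$gene, annotation$feature_kind)
  genes <- rownames(tab)
  out <- data.frame(
    gene = genes,
    m = as.integer(if ("probeset" %in% colnames(tab)) tab[, "probeset"] else 0L),
    n = as.integer(if ("probe" %in% colnames(tab)) tab[, "probe"] else 0L),
    stringsAsFactors = FALSE
  )
  out[order(out$gene), , drop = FALSE]
}

.CONFIDENCE_TRUE <- c("high", "High", "HIGH", "TRUE", "true", "T", "yes", "1")
.CONFIDENCE_FALSE <- c("low", "Low", "LOW", "FALSE", "false", "F", "no", "0",
                       "medium", "Medium")

#' Read an interaction edge list
#'
#' Loads an exported interaction table (e.g. a pathway-database export) and
#' applies the interaction-type and confidence filters at load time. Edges
#' are undirected: node pairs are canonicalized (lexicographically smaller
#' node first), duplicates collapsed, and self-loops dropped.
#'
#' @param path TSV/CSV with columns `node_a`, `node_b`, `interaction_type`,
#'   `confidence`.
#' @param allowed_types interaction types to keep; defaults to the
#'   high-accuracy trio used for induced network modules.
#' @param require_high_confidence drop edges whose confidence is not high.
#' @return data.frame with columns `node_a`, `node_b`, `interaction_type`,
#'   `high_confidence`, sorted by node pair.
#' @export
read_edge_list <- function(path,
                           allowed_types = c("binary_protein", "genetic", "regulatory"),
                           require_high_confidence = TRUE) {
  if (!file.exists(path)) .err("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = .sep_for(path), quote = "",
                          comment.char = "", colClasses = "character",
                          check.names = FALSE)
  need <- c("node_a", "node_b", "interaction_type", "confidence")
  miss <- setdiff(need, names(df))
  if (length(miss)) .err("edge list missing column(s): %s",
                         paste(miss, collapse = ", "))
  conf_in <- trimws(df$confidence)
  high <- conf_in %in% .CONFIDENCE_TRUE
  unknown <- !(conf_in %in% c(.CONFIDENCE_TRUE, .CONFIDENCE_FALSE))
  if (any(unknown))
    .err("unrecognized confidence value(s): %s",
         paste(unique(conf_in[unknown]), collapse = ", "))
  out <- data.frame(
    node_a = pmin(trimws(df$node_a), trimws(df$node_b)),
    node_b = pmax(trimws(df$node_a), trimws(df$node_b)),
    interaction_type = trimws(df$interaction_type),
    high_confidence = high,
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(out$node_a) | !nzchar(out$node_b)))
    .err("edge list contains empty node names")
  out <- out[out$node_a != out$node_b, , drop = FALSE]           # self-loops
  out <- out[out$interaction_type %in% allowed_types, , drop = FALSE]
  if (require_high_confidence) out <- out[out$high_confidence, , drop = FALSE]
  out <- unique(out)
  # collapse duplicate node pairs that differ only in annotation columns
  out <- out[!duplicated(out[, c("node_a", "node_b")]), , drop = FALSE]
  out <- out[order(out$node_a, out$node_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(v)
    ifelse(is.na(v), "NA", sprintf("%.10g", v)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write pipeline result tables
#'
#' Writes whichever result tables are present in `tables` as TSV files with
#' headers (`pair_fits.tsv`, `gene_summary.tsv`, `significant_genes.tsv`,
#' `probe_states.tsv`, `gene_meth_summary.tsv`, `hub_report.tsv`) plus a
#' `run_manifest.json` reproducibility manifest. The output directory is
#' created if missing. Numeric content is formatted deterministically, so a
#' rerun with the same configuration and seed is byte-identical.
#'
#' @param tables named list of data.frames; an optional `manifest` element
#'   (a list) is written as JSON.
#' @param out_dir output directory.
#' @return character vector of files written, invisibly.
#' @export
write_results <- function(tables, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) .err("cannot create output directory: %s", out_dir)
  known <- c("pair_fits", "gene_summary", "significant_genes", "probe_states",
             "gene_meth_summary", "hub_report", "truth")
  written <- character()
  for (nm in intersect(known, names(tables))) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    .write_tsv(tables[[nm]], p)
    written <- c(written, p)
  }
  if (!is.null(tables$manifest)) {
    p <- file.path(out_dir, "run_manifest.json")
    jsonlite::write_json(tables$manifest, p, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    written <- c(written, p)
  }
  invisible(written)
}
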