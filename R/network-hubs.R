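#' Build the induced subnetwork around an input gene list
#'
#' Constructs an undirected simple graph from a filtered edge list (see
#' [read_edge_list()]). Nodes are all edge endpoints plus all input genes;
#' input genes without any edge are retained as isolated nodes. Nodes not
#' on the input list — genes the network source added to connect inputs —
#' are marked intermediate.
#'
#' @param edges edge-list data.frame with columns `node_a`, `node_b`.
#' @param input_genes character vector of input gene symbols.
#' @return an [igraph::igraph] with a logical vertex attribute
#'   `is_intermediate`.
#' @export
build_subnetwork <- function(edges, input_genes) {
  endpoints <- unique(c(edges$node_a, edges$node_b))
  vertices <- data.frame(name = sort(union(endpoints, input_genes)),
                         stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges[, c("node_a", "node_b"), drop = FALSE],
    directed = FALSE, vertices = vertices
  )
  g <- igraph::simplify(g)
  igraph::V(g)$is_intermediate <- !(igraph::V(g)$name %in% input_genes)
  g
}

#' Identify hub genes by degree
#'
#' Hub genes are nodes with an unusually large number of connections. Two
#' reproducible rules are offered: `top_k` keeps the `k` highest-degree
#' nodes (all nodes tied with the k-th degree are included, so the result
#' does not depend on arbitrary tie-breaking), and `degree_min` keeps all
#' nodes with degree at least `degree_min`. The full degree table is always
#' returned with hubs flagged, so the ranking can be inspected directly.
#'
#' @param graph output of [build_subnetwork()].
#' @param mode `"top_k"` or `"degree_min"`.
#' @param k number of hubs for `top_k` (default 8).
#' @param degree_min minimum degree for `degree_min`.
#' @return data.frame sorted by (-degree, gene) with columns `gene`,
#'   `degree`, `is_intermediate`, `is_hub`.
#' @export
identify_hubs <- function(graph, mode = c("top_k", "degree_min"), k = 8,
                          degree_min = NULL) {
  mode <- match.arg(mode)
  deg <- igraph::degree(graph)
  out <- data.frame(gene = igraph::V(graph)$name,
                    degree = as.integer(deg),
                    is_intermediate = igraph::V(graph)$is_intermediate,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  if (mode == "top_k") {
    if (nrow(out) == 0L) .err("top_k hub selection needs a non-empty graph")
    if (!is.numeric(k) || k <= 0) .err("k must be a positive integer")
    kth <- out$degree[min(as.integer(k), nrow(out))]
    out$is_hub <- out$degree >= kth
  } else {
    if (is.null(degree_min)) .err("degree_min mode requires degree_min")
    out$is_hub <- out$degree >= degree_min
  }
  out
}

#' Profile hub genes against the pipeline's other outputs
#'
#' Joins each hub with its significant-list membership (`pos_final`,
#' `neg_final`, `intermediate`, or `input` for an input gene outside the
#' final lists), its direction implied by that membership, its per-gene
#' methylation-state summary, and whether all of its probesets sit below
#' the housekeeping expression level. Hubs without methylation or
#' expression information keep `NA` fields and are noted.
#'
#' @param hubs output of [identify_hubs()] (only rows with `is_hub` are
#'   profiled).
#' @param gene_lists a `significant_gene_lists` object from
#'   [build_lists()].
#' @param meth_summaries optional output of [summarize_meth_by_gene()].
#' @param expr_flags optional output of [flag_low_expression()].
#' @return data.frame with one row per hub.
#' @export
hub_profile <- function(hubs, gene_lists, meth_summaries = NULL,
                        expr_flags = NULL) {
  hub <- hubs[hubs$is_hub, , drop = FALSE]
  membership <- ifelse(hub$gene %in% gene_lists$pos_final, "pos_final",
                ifelse(hub$gene %in% gene_lists$neg_final, "neg_final",
                ifelse(hub$is_intermediate, "intermediate", "input")))
  direction <- ifelse(membership == "pos_final", "positive",
               ifelse(membership == "neg_final", "negative", "none"))
  out <- data.frame(gene = hub$gene, degree = hub$degree,
                    membership = membership, direction = direction,
                    stringsAsFactors = FALSE)
  meth_cols <- c("n_hyper", "n_hypo", "n_na", "pct_hyper", "pct_hypo", "pct_na")
  if (!is.null(meth_summaries)) {
    i <- match(out$gene, meth_summaries$gene)
    for (cn in meth_cols) out[[cn]] <- meth_summaries[[cn]][i]
    out$majority_hyper <- ifelse(is.na(i), NA,
      meth_summaries$n_hyper[i] >
        meth_summaries$n_hypo[i] + meth_summaries$n_na[i])
    absent <- out$gene[is.na(i)]
    if (length(absent))
      .msg("hub_profile: no methylation summary for: %s",
           paste(absent, collapse = ", "))
  } else {
    for (cn in meth_cols) out[[cn]] <- NA_real_
    out$majority_hyper <- NA
  }
  if (!is.null(expr_flags) && nrow(expr_flags)) {
    agg <- stats::aggregate(below_housekeeping ~ gene, data = expr_flags, FUN = all)
    i <- match(out$gene, agg$gene)
    out$all_probesets_low_expr <- agg$below_housekeeping[i]
  } else {
    out$all_probesets_low_expr <- NA
  }
  rownames(out) <- NULL
  out
}
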