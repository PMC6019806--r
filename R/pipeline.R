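#' Build and validate a pipeline run configuration
#'
#' A run configuration is the single source of truth for one end-to-end
#' analysis: either a `simulate` block (arguments for
#' [synthetic_config()]) or a `paths` block (named paths `expression`,
#' `methylation`, `phenotypes`, `annotation`, and optionally `edges`),
#' plus every tunable threshold of the analysis.
#'
#' @param simulate optional list of [synthetic_config()] arguments.
#' @param paths optional named list of input file paths.
#' @param alpha pair-level significance threshold.
#' @param alpha_norm Shapiro-Wilk exclusion threshold.
#' @param shapiro_adjust `"none"` or `"BH"`, see [shapiro_filter()].
#' @param anova `"marginal"` or `"sequential"`, see [fit_pair()].
#' @param probeset_cut,probe_cut length-class cuts, see
#'   [classify_gene_length()].
#' @param long_frac,short_frac significant-fraction thresholds.
#' @param coeff_cuts coefficient-magnitude cuts (first one feeds the final
#'   intersection).
#' @param housekeeping_threshold reference expression level.
#' @param hub_mode,hub_k,hub_degree_min hub selection, see
#'   [identify_hubs()].
#' @param allowed_edge_types,require_high_confidence edge-list filters, see
#'   [read_edge_list()].
#' @param seed integer seed for the simulate path.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(simulate = NULL, paths = NULL, alpha = 0.05,
                       alpha_norm = 0.05, shapiro_adjust = "none",
                       anova = "marginal", probeset_cut = 2, probe_cut = 20,
                       long_frac = 0.15, short_frac = 0.30,
                       coeff_cuts = c(0.5, 1), housekeeping_threshold = 8,
                       hub_mode = "top_k", hub_k = 8, hub_degree_min = NULL,
                       allowed_edge_types = c("binary_protein", "genetic", "regulatory"),
                       require_high_confidence = TRUE, seed = 1) {
  if (is.null(simulate) && is.null(paths))
    .err("run_config needs either a simulate block or input paths")
  for (a in c(alpha, alpha_norm))
    if (!is.numeric(a) || a <= 0 || a >= 1)
      .err("alpha and alpha_norm must lie in (0, 1)")
  if (any(c(probeset_cut, probe_cut, long_frac, short_frac, coeff_cuts,
            housekeeping_threshold) <= 0))
    .err("cutoffs must be positive")
  anova <- match.arg(anova, c("marginal", "sequential"))
  shapiro_adjust <- match.arg(shapiro_adjust, c("none", "BH"))
  hub_mode <- match.arg(hub_mode, c("top_k", "degree_min"))
  if (!is.null(paths)) {
    need <- c("expression", "methylation", "phenotypes", "annotation")
    miss <- setdiff(need, names(paths))
    if (length(miss)) .err("paths block missing: %s", paste(miss, collapse = ", "))
  }
  if (!is.null(simulate)) simulate$seed <- simulate$seed %||% seed
  structure(list(simulate = simulate, paths = paths, alpha = alpha,
                 alpha_norm = alpha_norm, shapiro_adjust = shapiro_adjust,
                 anova = anova, probeset_cut = probeset_cut,
                 probe_cut = probe_cut, long_frac = long_frac,
                 short_frac = short_frac, coeff_cuts = coeff_cuts,
                 housekeeping_threshold = housekeeping_threshold,
                 hub_mode = hub_mode, hub_k = hub_k,
                 hub_degree_min = hub_degree_min,
                 allowed_edge_types = allowed_edge_types,
                 require_high_confidence = require_high_confidence,
                 seed = as.integer(seed)),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full integration pipeline
#'
#' Executes the stages in order — load or simulate the matched datasets,
#' screen probesets for normality, fit all probeset-probe pair models,
#' summarize genes and build the significant-gene lists, classify probe
#' methylation states for the final genes, and (when an edge list is
#' supplied) identify hub genes in the induced subnetwork. A manifest
#' records the configuration, seed, package version, per-filter counts and
#' stage timings. With the same configuration and seed, the numeric
#' outputs are reproduced byte-identically.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory for [write_results()].
#' @return list of class `methexpr_result` with elements `data`,
#'   `normality`, `fits`, `summaries`, `lists`, `probe_states`,
#'   `gene_meth_summary`, `expr_flags`, `hubs`, `hub_profile`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "run_config")) .err("config must come from run_config()")
  timings <- list()
  tick <- function(expr, stage) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      .err("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  data <- tick(stage = "load", {
    if (!is.null(config$simulate)) {
      generate_dataset(do.call(synthetic_config, config$simulate))
    } else {
      p <- config$paths
      list(expression = read_matrix(p$expression),
           methylation = read_matrix(p$methylation),
           phenotypes = read_phenotypes(p$phenotypes),
           annotation = read_annotation(p$annotation),
           truth = NULL, n_clipped = NA_integer_)
    }
  })
  edges <- NULL
  if (!is.null(config$paths$edges))
    edges <- read_edge_list(config$paths$edges, config$allowed_edge_types,
                            config$require_high_confidence)

  normality <- tick(stage = "shapiro", shapiro_filter(
    data$expression, config$alpha_norm, config$shapiro_adjust))
  fits <- tick(stage = "fit", fit_all_pairs(
    data$expression, data$methylation, data$phenotypes, data$annotation,
    normality_reports = normality, anova = config$anova))
  summaries <- tick(stage = "summarize", summarize_genes(
    fits, data$annotation, alpha = config$alpha,
    long_frac = config$long_frac, short_frac = config$short_frac,
    probeset_cut = config$probeset_cut, probe_cut = config$probe_cut))
  lists <- tick(stage = "lists", build_lists(
    summaries, fits, alpha = config$alpha, coeff_cuts = config$coeff_cuts))

  states <- NULL; meth_sum <- NULL; flags <- NULL
  if (length(lists$all_final)) {
    states <- tick(stage = "methstate", probe_states(
      data$methylation, data$annotation, genes = lists$all_final,
      alpha = config$alpha))
    meth_sum <- summarize_meth_by_gene(states)
    flags <- flag_low_expression(data$expression, lists$all_final,
                                 data$annotation,
                                 config$housekeeping_threshold)
  }

  hubs <- NULL; profile <- NULL
  if (!is.null(edges)) {
    graph <- tick(stage = "hubs", build_subnetwork(edges, lists$all_final))
    hubs <- identify_hubs(graph, config$hub_mode, config$hub_k,
                          config$hub_degree_min)
    profile <- hub_profile(hubs, lists, meth_sum, flags)
  }

  manifest <- list(
    package = "methexpr",
    version = as.character(utils::packageVersion("methexpr")),
    seed = config$seed,
    config = config[setdiff(names(config), c("simulate", "paths"))],
    simulate = config$simulate,
    n_samples = nrow(data$phenotypes),
    n_genes = length(unique(data$annotation$gene)),
    n_probesets_excluded = sum(normality$excluded),
    n_clipped_expression_values = data$n_clipped,
    filter_counts = lists$filter_table,
    list_sizes = lists$list_table,
    stage_timings_sec = timings
  )

  result <- structure(list(
    data = data, normality = normality, fits = fits, summaries = summaries,
    lists = lists, probe_states = states, gene_meth_summary = meth_sum,
    expr_flags = flags, hubs = hubs, hub_profile = profile,
    manifest = manifest
  ), class = "methexpr_result")

  if (!is.null(out_dir)) {
    tables <- list(pair_fits = fits, gene_summary = summaries,
                   significant_genes = .lists_as_table(lists),
                   manifest = manifest)
    if (!is.null(states)) tables$probe_states <- states
    if (!is.null(meth_sum)) tables$gene_meth_summary <- meth_sum
    if (!is.null(hubs)) tables$hub_report <- hubs
    if (!is.null(data$truth)) tables$truth <- data$truth
    write_results(tables, out_dir)
  }
  invisible(result)
}

.lists_as_table <- function(lists) {
  sets <- c("pos_long", "pos_short", "neg_long", "neg_short", "pos_merged",
            "neg_merged", "pos_final", "neg_final", "all_final")
  do.call(rbind, lapply(sets, function(s) {
    g <- lists[[s]]
    if (!length(g)) return(NULL)
    data.frame(list = s, gene = g, stringsAsFactors = FALSE)
  })) %||% data.frame(list = character(), gene = character())
}

#' @export
print.methexpr_result <- function(x, ...) {
  cat("methexpr pipeline result\n")
  cat(sprintf("  samples: %d, genes: %d, pair fits: %d (%d ok)\n",
              x$manifest$n_samples, x$manifest$n_genes, nrow(x$fits),
              sum(x$fits$status == "ok")))
  cat(sprintf("  final gene lists: %d positive, %d negative (%d total)\n",
              length(x$lists$pos_final), length(x$lists$neg_final),
              length(x$lists$all_final)))
  if (!is.null(x$hubs))
    cat(sprintf("  hubs: %s\n",
                paste(x$hubs$gene[x$hubs$is_hub], collapse = ", ")))
  invisible(x)
}
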