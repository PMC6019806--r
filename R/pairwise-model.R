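#' @title Pairwise expression-methylation linear models
#' @description For every probeset-probe pair of a gene the model
#'   `y = beta0 + beta1*x + beta2*ER + beta3*subtype + eps` is fitted by
#'   ordinary least squares, where `y` is the probeset's log expression
#'   across samples and `x` the probe's M-value. ER and subtype enter as
#'   treatment-coded indicators (references: ERneg, Luminal). The reported
#'   p-value tests `beta1 = 0` adjusted for the covariates.
#' @name pairwise_model
NULL

# indicator covariates from a phenotype table (treatment coding,
# references ERneg / Luminal)
.covariate_matrix <- function(pheno) {
  Z <- cbind(
    ERpos = as.numeric(pheno$er_status == "ERpos"),
    BasalA = as.numeric(pheno$subtype == "BasalA"),
    BasalB = as.numeric(pheno$subtype == "BasalB")
  )
  rownames(Z) <- pheno$sample_id
  Z
}

.COEF_COLS <- c("beta0", "beta1", "beta2_ERpos", "beta3_BasalA", "beta3_BasalB")

.empty_fit <- function(n_used = 0L) {
  out <- as.list(rep(NA_real_, length(.COEF_COLS)))
  names(out) <- .COEF_COLS
  c(out, list(beta1_se = NA_real_, beta1_p = NA_real_,
              residual_df = NA_integer_, n_used = as.integer(n_used),
              status = "degenerate"))
}

# core OLS fit on one (y, x) pair against covariate matrix Z
.fit_pair_core <- function(y, x, Z, anova = "marginal") {
  keep <- is.finite(y) & is.finite(x)
  yk <- y[keep]; xk <- x[keep]; Zk <- Z[keep, , drop = FALSE]
  n <- length(yk)
  out <- .empty_fit(n)
  if (n < 2L || stats::var(xk) == 0) return(out)
  # drop indicator columns for phenotype levels absent among kept samples
  usable <- apply(Zk, 2L, function(col) length(unique(col)) > 1L)
  Zu <- Zk[, usable, drop = FALSE]
  X <- cbind(`(Intercept)` = rep(1, n), meth = xk, Zu)
  p <- ncol(X)
  if (n <= p) return(out)
  fit <- stats::lm.fit(X, yk)
  if (fit$rank < p) return(out)                     # collinear design
  beta <- fit$coefficients
  out$beta0 <- unname(beta["(Intercept)"])
  out$beta1 <- unname(beta["meth"])
  if ("ERpos" %in% names(beta)) out$beta2_ERpos <- unname(beta["ERpos"])
  if ("BasalA" %in% names(beta)) out$beta3_BasalA <- unname(beta["BasalA"])
  if ("BasalB" %in% names(beta)) out$beta3_BasalB <- unname(beta["BasalB"])
  df <- n - p
  out$residual_df <- as.integer(df)
  rss <- sum(fit$residuals^2)
  if (rss <= 1e-10 * max(sum(yk^2), 1e-8)) return(out)  # perfect fit
  sigma2 <- rss / df
  R <- qr.R(fit$qr)
  XtXinv <- chol2inv(R)
  # lm.fit pivots; map the inverse back to design-column order
  ord <- order(fit$qr$pivot)
  se_all <- sqrt(sigma2 * diag(XtXinv)[ord])
  names(se_all) <- colnames(X)
  out$beta1_se <- unname(se_all["meth"])
  if (anova == "sequential") {
    # sequential (Type I) sum of squares for the methylation term fitted
    # first, tested against the full-model mean square error
    rss0 <- sum(qr.resid(qr(X[, 1L, drop = FALSE]), yk)^2)
    rss1 <- sum(qr.resid(qr(X[, 1:2, drop = FALSE]), yk)^2)
    Fst <- (rss0 - rss1) / sigma2
    out$beta1_p <- stats::pf(Fst, 1, df, lower.tail = FALSE)
  } else {
    tstat <- out$beta1 / out$beta1_se
    out$beta1_p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  }
  out$status <- "ok"
  out
}

#' Fit the covariate-adjusted linear model to one probeset-probe pair
#'
#' Ordinary least squares of expression on methylation with ER status and
#' tumour subtype as adjustment covariates. Samples with a missing value in
#' either `y` or `x` are dropped (pairwise deletion); phenotype levels
#' absent among the remaining samples lose their indicator column (reduced
#' design). The default `beta1_p` is the marginal two-sided t-test of the
#' methylation coefficient from the full model; `anova = "sequential"`
#' instead reports the sequential ANOVA p-value with the methylation term
#' fitted first.
#'
#' Degenerate situations — constant methylation, a collinear or
#' over-saturated design, or a perfect fit (zero residual variance) — are
#' reported with `status = "degenerate"` and `beta1_p` unset (coefficients
#' are still reported when estimable).
#'
#' @param y expression values; if named, names must match
#'   `pheno$sample_id`.
#' @param x methylation M-values, aligned like `y`.
#' @param pheno a [phenotype_table()].
#' @param anova `"marginal"` (default) or `"sequential"`.
#' @return one-row data.frame with columns `beta0`, `beta1`, `beta2_ERpos`,
#'   `beta3_BasalA`, `beta3_BasalB`, `beta1_se`, `beta1_p`, `residual_df`,
#'   `n_used`, `status`.
#' @export
fit_pair <- function(y, x, pheno, anova = c("marginal", "sequential")) {
  anova <- match.arg(anova)
  ids <- pheno$sample_id
  align <- function(v, what) {
    if (!is.null(names(v))) {
      if (!setequal(names(v), ids))
        .err("%s sample IDs do not match the phenotype table", what)
      v <- v[ids]
    } else if (length(v) != length(ids)) {
      .err("%s has %d values for %d samples", what, length(v), length(ids))
    }
    as.numeric(v)
  }
  y <- align(y, "y"); x <- align(x, "x")
  res <- .fit_pair_core(y, x, .covariate_matrix(pheno), anova)
  as.data.frame(res, stringsAsFactors = FALSE)
}

#' Shapiro-Wilk normality screen for expression probesets
#'
#' Linear-model inference assumes approximately normal residuals; probesets
#' whose expression distribution departs strongly from normality are
#' excluded from pair enumeration. Each probeset's non-missing values are
#' tested with [stats::shapiro.test()]; a probeset is excluded when its
#' (optionally BH-adjusted) p-value falls below `alpha_norm`. Probesets with
#' fewer than 3 usable values or zero variance cannot be tested and are
#' excluded with `shapiro_p` unset.
#'
#' @param expr expression [omics_matrix()] (probesets x samples).
#' @param alpha_norm exclusion threshold on the normality p-value.
#' @param p_adjust `"none"` (default) for raw p-values or `"BH"` for
#'   Benjamini-Hochberg adjusted p-values.
#' @return data.frame with columns `probeset_id`, `shapiro_p`, `excluded`,
#'   `reason`.
#' @export
shapiro_filter <- function(expr, alpha_norm = 0.05,
                           p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (alpha_norm < 0 || alpha_norm > 1) .err("alpha_norm must lie in [0, 1]")
  ids <- rownames(expr)
  praw <- rep(NA_real_, length(ids))
  reason <- rep("", length(ids))
  for (i in seq_along(ids)) {
    v <- expr[i, ]
    v <- v[is.finite(v)]
    if (length(v) < 3L) {
      reason[i] <- "fewer than 3 non-missing values"
    } else if (stats::var(v) == 0) {
      reason[i] <- "zero variance"
    } else {
      praw[i] <- stats::shapiro.test(v)$p.value
    }
  }
  p <- if (p_adjust == "BH") stats::p.adjust(praw, "BH") else praw
  excluded <- ifelse(is.na(p), TRUE, p < alpha_norm)
  reason[excluded & reason == ""] <- "normality rejected"
  n_untestable <- sum(is.na(p))
  if (n_untestable > 0L)
    .msg("shapiro_filter: %d probeset(s) untestable and excluded", n_untestable)
  data.frame(probeset_id = ids, shapiro_p = p, excluded = excluded,
             reason = reason, stringsAsFactors = FALSE)
}

#' Fit the pairwise model to all probeset-probe pairs of all genes
#'
#' Enumerates, for every gene in the annotation, all `m' x n` pairs of its
#' normality-surviving probesets with its methylation probes, and fits each
#' pair with [fit_pair()]'s model. Genes whose probesets are all excluded
#' contribute no pairs (they are logged). Output rows are ordered
#' lexicographically by (gene, probeset, probe).
#'
#' @param expr,meth expression and methylation [omics_matrix()] objects
#'   sharing the phenotype table's sample set.
#' @param pheno a [phenotype_table()].
#' @param annotation a [gene_annotation()].
#' @param normality_reports optional output of [shapiro_filter()]; excluded
#'   probesets are removed from pair enumeration. `NULL` applies no filter.
#' @param anova passed to the per-pair fit; see [fit_pair()].
#' @return data.frame of pair fits with columns `gene`, `probeset_id`,
#'   `probe_id` plus the [fit_pair()] columns.
#' @export
fit_all_pairs <- function(expr, meth, pheno, annotation,
                          normality_reports = NULL,
                          anova = c("marginal", "sequential")) {
  anova <- match.arg(anova)
  ids <- pheno$sample_id
  if (!setequal(colnames(expr), ids) || !setequal(colnames(meth), ids))
    .err("expression/methylation sample IDs do not match the phenotype table")
  expr <- expr[, ids, drop = FALSE]
  meth <- meth[, ids, drop = FALSE]
  Z <- .covariate_matrix(pheno)

  excluded_ps <- character()
  if (!is.null(normality_reports))
    excluded_ps <- normality_reports$probeset_id[normality_reports$excluded]

  ann_ps <- annotation[annotation$feature_kind == "probeset", ]
  ann_pr <- annotation[annotation$feature_kind == "probe", ]
  missing_feat <- c(setdiff(ann_ps$feature_id, rownames(expr)),
                    setdiff(ann_pr$feature_id, rownames(meth)))
  if (length(missing_feat))
    .err("annotation feature(s) absent from the matrices: %s",
         paste(utils::head(missing_feat, 5L), collapse = ", "))

  genes <- sort(unique(annotation$gene))
  chunks <- vector("list", length(genes))
  n_dropped <- 0L
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    ps <- sort(setdiff(ann_ps$feature_id[ann_ps$gene == g], excluded_ps))
    pr <- sort(ann_pr$feature_id[ann_pr$gene == g])
    if (length(ps) == 0L || length(pr) == 0L) {
      n_dropped <- n_dropped + 1L
      next
    }
    rows <- vector("list", length(ps) * length(pr))
    r <- 0L
    for (p_id in ps) {
      y <- expr[p_id, ]
      for (q_id in pr) {
        r <- r + 1L
        fitrow <- .fit_pair_core(y, meth[q_id, ], Z, anova)
        rows[[r]] <- c(list(gene = g, probeset_id = p_id, probe_id = q_id),
                       fitrow)
      }
    }
    chunks[[gi]] <- rows
  }
  if (n_dropped > 0L)
    .msg("fit_all_pairs: %d gene(s) with no usable probesets dropped from pair output",
         n_dropped)
  rows <- unlist(chunks, recursive = FALSE)
  if (is.null(rows) || length(rows) == 0L) {
    cols <- c("gene", "probeset_id", "probe_id", .COEF_COLS,
              "beta1_se", "beta1_p", "residual_df", "n_used", "status")
    out <- as.data.frame(matrix(nrow = 0L, ncol = length(cols)))
    names(out) <- cols
    return(out)
  }
  fld <- function(nm, proto) vapply(rows, function(r) r[[nm]], proto)
  out <- data.frame(
    gene = fld("gene", character(1L)),
    probeset_id = fld("probeset_id", character(1L)),
    probe_id = fld("probe_id", character(1L)),
    beta0 = fld("beta0", numeric(1L)),
    beta1 = fld("beta1", numeric(1L)),
    beta2_ERpos = fld("beta2_ERpos", numeric(1L)),
    beta3_BasalA = fld("beta3_BasalA", numeric(1L)),
    beta3_BasalB = fld("beta3_BasalB", numeric(1L)),
    beta1_se = fld("beta1_se", numeric(1L)),
    beta1_p = fld("beta1_p", numeric(1L)),
    residual_df = fld("residual_df", integer(1L)),
    n_used = fld("n_used", integer(1L)),
    status = fld("status", character(1L)),
    stringsAsFactors = FALSE
  )
  out
}
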