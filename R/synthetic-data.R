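#' Configuration for the synthetic expression/methylation generator
#'
#' Defines the study conditions the generator emulates: a panel of 40 cell
#' lines with binary estrogen-receptor (ER) status and a three-level tumour
#' subtype, an expression matrix in the RMA log-abundance range \[2, 13.5\],
#' and a methylation M-value matrix whose values lie (almost) within
#' \[-4, 4\]. Each gene carries `m` probesets and `n` probes; a latent
#' per-sample gene-level methylation signal `t[g,s] ~ N(mu_g, meth_sd^2)` is
#' shared by all of the gene's probes, which observe it with probe-level
#' noise of standard deviation `probe_sd` (optionally equicorrelated across
#' probes with coefficient `rho`). Expression of each probeset responds to
#' the latent signal with a gene-specific methylation coefficient `beta1`,
#' plus ER and subtype effects and Gaussian residual noise.
#'
#' @param n_samples number of cell lines (default 40).
#' @param n_genes number of genes.
#' @param m_range integer range (inclusive) of probesets per gene.
#' @param n_range integer range (inclusive) of probes per gene.
#' @param frac_positive,frac_negative fractions of genes with true
#'   methylation effect `+beta1_magnitude` / `-beta1_magnitude`; the
#'   remainder are null (`beta1 = 0`).
#' @param beta1_magnitude absolute true methylation coefficient of
#'   non-null genes (log2 expression units per M-value unit).
#' @param beta0_range range of per-probeset baseline expression.
#' @param beta2 ER effect (ERpos vs ERneg) on expression.
#' @param beta3_vec named numeric of subtype effects relative to the Luminal
#'   reference level (`BasalA`, `BasalB`).
#' @param sigma residual SD of expression (> 0).
#' @param meth_mu_range range of the per-gene mean M-value.
#' @param meth_sd SD of the latent per-sample gene-level methylation signal
#'   (>= 0; 0 isolates the probe-noise layer).
#' @param probe_sd SD of probe-level measurement noise around the latent
#'   signal (> 0).
#' @param rho equicorrelation of the probe-level noise across a gene's
#'   probes; must exceed `-1/(n_probes - 1)` for every gene.
#' @param expr_clip interval expression values are clipped to.
#' @param seed integer seed; the generator is fully reproducible from it.
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 40, n_genes = 100,
                             m_range = c(1, 3), n_range = c(5, 30),
                             frac_positive = 0.3, frac_negative = 0.3,
                             beta1_magnitude = 1, beta0_range = c(6, 9),
                             beta2 = 0.8,
                             beta3_vec = c(BasalA = 0.4, BasalB = -0.4),
                             sigma = 1,
                             meth_mu_range = c(-1, 1), meth_sd = 1,
                             probe_sd = 0.1, rho = 0,
                             expr_clip = c(2, 13.5), seed = 1) {
  cfg <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
              m_range = as.integer(m_range), n_range = as.integer(n_range),
              frac_positive = frac_positive, frac_negative = frac_negative,
              beta1_magnitude = beta1_magnitude, beta0_range = beta0_range,
              beta2 = beta2, beta3_vec = beta3_vec, sigma = sigma,
              meth_mu_range = meth_mu_range, meth_sd = meth_sd,
              probe_sd = probe_sd, rho = rho, expr_clip = expr_clip,
              seed = as.integer(seed))
  ok_interval <- function(x) length(x) == 2L && !anyNA(x) && x[1] <= x[2]
  if (cfg$n_samples < 1L || cfg$n_genes < 1L)
    .err("n_samples and n_genes must be positive")
  for (nm in c("m_range", "n_range", "beta0_range", "meth_mu_range", "expr_clip"))
    if (!ok_interval(cfg[[nm]])) .err("%s must be an ordered interval", nm)
  if (cfg$m_range[1] < 1L || cfg$n_range[1] < 1L)
    .err("m_range and n_range must start at 1 or more")
  if (cfg$frac_positive < 0 || cfg$frac_negative < 0 ||
      cfg$frac_positive + cfg$frac_negative > 1)
    .err("frac_positive + frac_negative must lie in [0, 1]")
  if (cfg$sigma <= 0) .err("sigma must be > 0")
  if (cfg$meth_sd < 0) .err("meth_sd must be >= 0")
  if (cfg$probe_sd <= 0) .err("probe_sd must be > 0")
  if (cfg$rho <= -1 || cfg$rho >= 1) .err("rho must lie in (-1, 1)")
  if (!all(c("BasalA", "BasalB") %in% names(cfg$beta3_vec)))
    .err("beta3_vec needs named elements BasalA and BasalB")
  class(cfg) <- "synthetic_config"
  cfg
}

# n_probes x n_samples matrix of probe noise with equicorrelation rho
.probe_noise <- function(n_probes, n_samples, probe_sd, rho) {
  Z <- matrix(stats::rnorm(n_probes * n_samples), n_probes, n_samples)
  if (rho == 0 || n_probes == 1L) return(probe_sd * Z)
  if (rho <= -1 / (n_probes - 1))
    .err("rho = %.3f is not a valid equicorrelation for %d probes", rho, n_probes)
  C <- matrix(rho, n_probes, n_probes)
  diag(C) <- 1
  probe_sd * crossprod(chol(C), Z)
}

#' Generate a matched synthetic expression/methylation dataset
#'
#' Samples receive ER status Bernoulli(0.5) and a uniform three-level
#' subtype. For each gene, a mean M-value `mu_g` is drawn uniformly from
#' `meth_mu_range`; the latent per-sample methylation signal is
#' `t[g,s] = mu_g + meth_sd * z[g,s]`, observed by each probe with added
#' probe-level noise (see [synthetic_config()]). Each probeset's expression
#' is `beta0 + beta1 * t[g,s] + beta2 * ER + beta3[subtype] + eps`, clipped
#' to `expr_clip`; clipping events are counted in the output.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `expression` and `methylation`
#'   ([omics_matrix()]), `phenotypes` ([phenotype_table()]), `annotation`
#'   ([gene_annotation()]), `truth` (data.frame: `gene`, `true_direction`,
#'   `true_beta1`, `m`, `n`) and `n_clipped` (count of clipped expression
#'   values).
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, config)
  cfg <- config
  set.seed(cfg$seed)
  ns <- cfg$n_samples
  samples <- sprintf("S%02d", seq_len(ns))

  pheno <- phenotype_table(data.frame(
    sample_id = samples,
    er_status = ifelse(stats::rbinom(ns, 1, 0.5) == 1, "ERpos", "ERneg"),
    subtype = sample(c("Luminal", "BasalA", "BasalB"), ns, replace = TRUE),
    stringsAsFactors = FALSE
  ))
  cov_shift <- cfg$beta2 * (pheno$er_status == "ERpos") +
    cfg$beta3_vec["BasalA"] * (pheno$subtype == "BasalA") +
    cfg$beta3_vec["BasalB"] * (pheno$subtype == "BasalB")
  cov_shift <- as.numeric(cov_shift)

  ng <- cfg$n_genes
  genes <- sprintf("G%03d", seq_len(ng))
  n_pos <- round(cfg$frac_positive * ng)
  n_neg <- round(cfg$frac_negative * ng)
  direction <- c(rep("positive", n_pos), rep("negative", n_neg),
                 rep("null", ng - n_pos - n_neg))
  beta1 <- ifelse(direction == "positive", cfg$beta1_magnitude,
                  ifelse(direction == "negative", -cfg$beta1_magnitude, 0))
  m_choices <- seq(cfg$m_range[1], cfg$m_range[2])
  n_choices <- seq(cfg$n_range[1], cfg$n_range[2])
  m_per <- m_choices[sample.int(length(m_choices), ng, replace = TRUE)]
  n_per <- n_choices[sample.int(length(n_choices), ng, replace = TRUE)]

  expr_rows <- vector("list", ng)
  meth_rows <- vector("list", ng)
  annot_rows <- vector("list", ng)
  n_clipped <- 0L
  lo <- cfg$expr_clip[1]; hi <- cfg$expr_clip[2]

  for (g in seq_len(ng)) {
    m <- m_per[g]; n <- n_per[g]
    mu_g <- stats::runif(1, cfg$meth_mu_range[1], cfg$meth_mu_range[2])
    t_gs <- mu_g + cfg$meth_sd * stats::rnorm(ns)
    M <- matrix(t_gs, n, ns, byrow = TRUE) +
      .probe_noise(n, ns, cfg$probe_sd, cfg$rho)
    rownames(M) <- sprintf("%s_pr%03d", genes[g], seq_len(n))

    beta0 <- stats::runif(m, cfg$beta0_range[1], cfg$beta0_range[2])
    E <- matrix(NA_real_, m, ns,
                dimnames = list(sprintf("%s_ps%d", genes[g], seq_len(m)), NULL))
    for (k in seq_len(m)) {
      y <- beta0[k] + beta1[g] * t_gs + cov_shift + cfg$sigma * stats::rnorm(ns)
      n_clipped <- n_clipped + sum(y < lo | y > hi)
      E[k, ] <- pmin(pmax(y, lo), hi)
    }
    expr_rows[[g]] <- E
    meth_rows[[g]] <- M
    annot_rows[[g]] <- data.frame(
      gene = genes[g],
      feature_id = c(rownames(E), rownames(M)),
      feature_kind = rep(c("probeset", "probe"), c(m, n)),
      stringsAsFactors = FALSE
    )
  }

  expr <- do.call(rbind, expr_rows)
  colnames(expr) <- samples
  meth <- do.call(rbind, meth_rows)
  colnames(meth) <- samples

  list(
    expression = omics_matrix(expr),
    methylation = omics_matrix(meth),
    phenotypes = pheno,
    annotation = gene_annotation(do.call(rbind, annot_rows)),
    truth = data.frame(gene = genes, true_direction = direction,
                       true_beta1 = beta1, m = m_per, n = n_per,
                       stringsAsFactors = FALSE),
    n_clipped = n_clipped
  )
}

#' Confusion matrix of called vs true gene directions
#'
#' Compares the direction calls of a gene-level summary (see
#' [summarize_genes()]) against the generator's ground truth. A summary
#' direction of `"none"` is counted as a null call.
#'
#' @param summary data.frame with columns `gene` and `direction`.
#' @param truth truth table from [generate_dataset()].
#' @return 3x3 integer matrix (rows = truth, columns = called) over
#'   \{positive, negative, null\}.
#' @export
truth_confusion <- function(summary, truth) {
  if (!setequal(summary$gene, truth$gene))
    .err("summary and truth cover different gene sets")
  lv <- c("positive", "negative", "null")
  called <- summary$direction[match(truth$gene, summary$gene)]
  called[called == "none"] <- "null"
  tab <- table(factor(truth$true_direction, levels = lv),
               factor(called, levels = lv))
  out <- matrix(as.integer(tab), 3, 3, dimnames = list(truth = lv, called = lv))
  out
}
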