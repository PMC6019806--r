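test_that("fit_pair matches the normal-equations + t-distribution oracle", {
  # small hand-chosen integers, n = 8, all four coefficient groups present
  pheno <- phenotype_table(data.frame(
    sample_id = paste0("S", 1:8),
    er_status = c("ERpos", "ERneg", "ERpos", "ERneg", "ERpos", "ERneg",
                  "ERpos", "ERneg"),
    subtype = c("Luminal", "Luminal", "BasalA", "BasalA", "BasalB", "BasalB",
                "Luminal", "BasalA")
  ))
  y <- c(5, 3, 6, 2, 7, 4, 5, 3)
  x <- c(1, -1, 2, 0, 3, -2, 1, 0)
  fit <- fit_pair(y, x, pheno)
  orc <- oracle_ols(y, x, pheno)
  expect_equal(fit$beta1, unname(orc$beta1), tolerance = 1e-10)
  expect_equal(fit$beta1_se, unname(orc$beta1_se), tolerance = 1e-10)
  expect_equal(fit$beta1_p, unname(orc$beta1_p), tolerance = 1e-10)
  expect_equal(fit$residual_df, orc$residual_df)

  # random pairs, with missing values, against the oracle
  set.seed(101)
  ph40 <- make_pheno(40, seed = 6)
  for (i in 1:40) {
    y <- rnorm(40, 7, 1.5); x <- rnorm(40, 0, 1.2)
    if (i %% 3 == 0) y[sample(40, 3)] <- NA
    if (i %% 4 == 0) x[sample(40, 2)] <- NA
    fit <- fit_pair(y, x, ph40)
    orc <- oracle_ols(y, x, ph40)
    expect_equal(fit$beta1, unname(orc$beta1), tolerance = 1e-8)
    expect_equal(fit$beta1_se, unname(orc$beta1_se), tolerance = 1e-8)
    expect_equal(fit$beta1_p, unname(orc$beta1_p), tolerance = 1e-8)
    expect_equal(fit$n_used, orc$n_used)
  }
})

test_that("degenerate designs are detected and labelled", {
  n <- 10
  pheno <- phenotype_table(data.frame(
    sample_id = paste0("S", 1:n), er_status = "ERpos", subtype = "Luminal"))
  x <- seq_len(n)
  # exact linear relation, covariate levels all dropped: perfect fit
  fit <- fit_pair(2 + 1.5 * x, x, pheno)
  expect_equal(fit$status, "degenerate")
  expect_equal(fit$beta1, 1.5)
  expect_true(is.na(fit$beta1_p))

  # constant methylation
  fit2 <- fit_pair(rnorm(n), rep(2, n), pheno)
  expect_equal(fit2$status, "degenerate")

  # too few samples after pairwise deletion
  ph <- make_pheno(6, seed = 2)
  y <- rnorm(6); y[1:4] <- NA
  fit3 <- fit_pair(y, rnorm(6), ph)
  expect_equal(fit3$status, "degenerate")
  expect_equal(fit3$n_used, 2L)

  # mismatched sample IDs
  yn <- stats::setNames(rnorm(6), paste0("X", 1:6))
  expect_error(fit_pair(yn, rnorm(6), ph), "sample IDs")
})

test_that("sequential ANOVA option reproduces stats::anova term ordering", {
  set.seed(55)
  ph <- make_pheno(30, seed = 9)
  y <- rnorm(30, 7); x <- rnorm(30)
  fit <- fit_pair(y, x, ph, anova = "sequential")
  df <- data.frame(y = y, x = x,
                   er = factor(ph$er_status, c("ERneg", "ERpos")),
                   sub = factor(ph$subtype, c("Luminal", "BasalA", "BasalB")))
  ref <- stats::anova(stats::lm(y ~ x + er + sub, df))["x", "Pr(>F)"]
  expect_equal(fit$beta1_p, ref, tolerance = 1e-10)
  # sequential p with methylation first differs from the adjusted test
  expect_false(isTRUE(all.equal(fit$beta1_p, fit_pair(y, x, ph)$beta1_p)))
})

test_that("shapiro_filter keeps normal probesets and rejects two-point ones", {
  set.seed(12)
  norm_mat <- omics_matrix(matrix(rnorm(200 * 40), 200, 40,
    dimnames = list(sprintf("ps%03d", 1:200), sprintf("S%02d", 1:40))))
  rep_norm <- shapiro_filter(norm_mat)
  expect_gte(mean(!rep_norm$excluded), 0.90)
  # excluded iff p < alpha
  expect_identical(rep_norm$excluded, rep_norm$shapiro_p < 0.05)

  two_point <- omics_matrix(matrix(sample(c(0, 10), 40, TRUE), 1, 40,
    dimnames = list("ps_bi", sprintf("S%02d", 1:40))))
  expect_true(shapiro_filter(two_point)$excluded)
  expect_lt(shapiro_filter(two_point)$shapiro_p,
            stats::shapiro.test(two_point[1, ])$p.value + 1e-12)

  # alpha 0 excludes nothing testable; untestable probesets always excluded
  expect_false(any(shapiro_filter(norm_mat, alpha_norm = 0)$excluded))
  short <- omics_matrix(matrix(c(1, 2, NA, NA), 1, 4,
    dimnames = list("ps_short", paste0("S", 1:4))))
  rep_short <- suppressMessages(shapiro_filter(short, alpha_norm = 0.05))
  expect_true(rep_short$excluded)
  expect_true(is.na(rep_short$shapiro_p))
})

test_that("fit_all_pairs enumerates m' x n pairs in deterministic order", {
  d <- generate_dataset(synthetic_config(
    n_genes = 2, m_range = c(3, 3), n_range = c(25, 25), seed = 31))
  fits <- fit_all_pairs(d$expression, d$methylation, d$phenotypes,
                        d$annotation)
  expect_equal(nrow(fits), 2 * 3 * 25)
  expect_identical(fits, fits[order(fits$gene, fits$probeset_id,
                                    fits$probe_id), ])

  # excluding one probeset of one gene removes its 25 pairs
  nr <- data.frame(probeset_id = "G001_ps1", shapiro_p = 0.001,
                   excluded = TRUE)
  fits2 <- fit_all_pairs(d$expression, d$methylation, d$phenotypes,
                         d$annotation, normality_reports = nr)
  expect_equal(nrow(fits2), 75 + 50)
  expect_false("G001_ps1" %in% fits2$probeset_id)

  # pair coefficients match an independent per-pair oracle refit
  idx <- seq(1, nrow(fits), by = 15)
  for (i in idx) {
    orc <- oracle_ols(d$expression[fits$probeset_id[i], ],
                      d$methylation[fits$probe_id[i], ], d$phenotypes)
    expect_equal(fits$beta1[i], unname(orc$beta1), tolerance = 1e-8)
    expect_equal(fits$beta1_p[i], unname(orc$beta1_p), tolerance = 1e-8)
  }
})

test_that("significant-pair fraction grows with the true effect size", {
  frac_sig <- vapply(c(0, 0.5, 1), function(b1) {
    d <- generate_dataset(synthetic_config(
      n_genes = 60, m_range = c(1, 1), n_range = c(1, 1),
      frac_positive = if (b1 > 0) 1 else 0, frac_negative = 0,
      beta1_magnitude = max(b1, 1), seed = 77))   # paired seed across levels
    fits <- fit_all_pairs(d$expression, d$methylation, d$phenotypes,
                          d$annotation)
    mean(fits$beta1_p[fits$status == "ok"] < 0.05)
  }, numeric(1))
  # beta1 = 0.5 via magnitude scaling on the same seed
  d_half <- generate_dataset(synthetic_config(
    n_genes = 60, m_range = c(1, 1), n_range = c(1, 1), frac_positive = 1,
    frac_negative = 0, beta1_magnitude = 0.5, seed = 77))
  f_half <- fit_all_pairs(d_half$expression, d_half$methylation,
                          d_half$phenotypes, d_half$annotation)
  frac_sig[2] <- mean(f_half$beta1_p[f_half$status == "ok"] < 0.05)
  expect_true(all(diff(frac_sig) >= -0.02))
  expect_lt(frac_sig[1], 0.15)
  expect_gt(frac_sig[3], 0.9)
})
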