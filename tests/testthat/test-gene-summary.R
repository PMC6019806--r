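test_that("length classification uses strict cuts on probesets and probes", {
  expect_equal(classify_gene_length(3, 5), "long")    # m > 2
  expect_equal(classify_gene_length(1, 21), "long")   # n > 20
  expect_equal(classify_gene_length(2, 20), "short")  # neither strict
  expect_equal(classify_gene_length(c(3, 1, 2), c(5, 21, 20)),
               c("long", "long", "short"))
  expect_error(classify_gene_length(0, 5), ">= 1")
})

test_that("gene summaries apply strict fraction and majority rules", {
  # long gene, 20 pairs, 4 significant: 0.20 > 0.15 passes
  f <- make_fits("G1", beta1 = rep(1, 20),
                 beta1_p = c(rep(0.01, 4), rep(0.5, 16)))
  s <- summarize_gene(f, m = 3, n = 5)
  expect_equal(s$length_class, "long")
  expect_equal(s$frac_sig, 0.20)
  expect_true(s$passes_frac_threshold)
  expect_equal(s$direction, "positive")

  # exactly half positive, half negative: no direction
  f2 <- make_fits("G2", beta1 = rep(c(1, -1), 5), beta1_p = rep(0.01, 10))
  expect_equal(summarize_gene(f2, m = 1, n = 10)$direction, "none")

  # short gene at exactly the threshold fails the strict rule
  f3 <- make_fits("G3", beta1 = rep(1, 10),
                  beta1_p = c(rep(0.01, 3), rep(0.5, 7)))
  s3 <- summarize_gene(f3, m = 1, n = 10)
  expect_equal(s3$length_class, "short")
  expect_equal(s3$frac_sig, 0.30)
  expect_false(s3$passes_frac_threshold)

  # degenerate fits are excluded from numerator and denominator
  f4 <- make_fits("G4", beta1 = rep(1, 4), beta1_p = rep(0.01, 4),
                  status = c("ok", "ok", "degenerate", "degenerate"))
  s4 <- summarize_gene(f4, m = 1, n = 4)
  expect_equal(s4$n_pairs, 2L)
  expect_equal(s4$frac_sig, 1)

  # all-degenerate gene is reported flagged with no direction
  f5 <- make_fits("G5", beta1 = rep(1, 3), beta1_p = rep(NA_real_, 3),
                  status = "degenerate")
  s5 <- summarize_gene(f5, m = 1, n = 3)
  expect_equal(s5$n_pairs, 0L)
  expect_equal(s5$direction, "none")
  expect_true(s5$flagged)
})

test_that("coefficient filters match a brute-force scan", {
  f <- make_fits("G1", beta1 = c(0.6, 0.4, 1.2), beta1_p = rep(0.01, 3))
  expect_equal(coeff_filter(f, 0.5, "pos")$n_pairs, 2L)
  expect_equal(coeff_filter(f, 1, "pos")$n_pairs, 1L)
  expect_equal(coeff_filter(f, 0.5, "pos")$threshold_label, "gt0.5")
  expect_equal(coeff_filter(f, 0.5, "neg")$threshold_label, "ltm0.5")

  set.seed(88)
  fits <- do.call(rbind, lapply(sprintf("G%02d", 1:10), function(g)
    make_fits(g, beta1 = rnorm(5, 0, 1), beta1_p = runif(5))))
  for (cut in c(0.5, 1)) for (sg in c("pos", "neg")) {
    res <- coeff_filter(fits, cut, sg)
    keep <- if (sg == "pos") fits$beta1 > cut else fits$beta1 < -cut
    keep <- keep & fits$beta1_p < 0.05
    expect_equal(res$n_pairs, sum(keep))
    expect_setequal(res$genes, unique(fits$gene[keep]))
    expect_lte(length(res$genes), res$n_pairs)   # unique-gene bound
  }
})

test_that("monotonicity: stricter cuts never enlarge results", {
  set.seed(13)
  fits <- do.call(rbind, lapply(sprintf("G%02d", 1:15), function(g)
    make_fits(g, beta1 = rnorm(8), beta1_p = runif(8))))
  cuts <- c(0.2, 0.5, 0.8, 1.2)
  np <- vapply(cuts, function(ct) coeff_filter(fits, ct, "pos")$n_pairs,
               integer(1))
  ng <- vapply(cuts, function(ct)
    length(coeff_filter(fits, ct, "pos")$genes), integer(1))
  expect_true(all(diff(np) <= 0))
  expect_true(all(diff(ng) <= 0))

  ann <- data.frame(gene = rep(sprintf("G%02d", 1:15), each = 2),
                    feature_id = c(rbind(sprintf("G%02d_ps1", 1:15),
                                         sprintf("G%02d_pr1", 1:15))),
                    feature_kind = rep(c("probeset", "probe"), 15))
  # raising the fraction thresholds never grows the passing set
  passing <- vapply(c(0.1, 0.3, 0.6), function(fr)
    sum(summarize_genes(fits, ann, long_frac = fr, short_frac = fr)
        $passes_frac_threshold), integer(1))
  expect_true(all(diff(passing) <= 0))
})

test_that("merging long and short lists reproduces the worked sizes", {
  long_pos <- sprintf("LP%03d", 1:165); short_pos <- sprintf("SP%03d", 1:89)
  expect_length(merge_long_short(long_pos, short_pos), 254)
  long_neg <- sprintf("LN%03d", 1:95); short_neg <- sprintf("SN%03d", 1:87)
  expect_length(merge_long_short(long_neg, short_neg), 182)
  expect_length(merge_long_short(character(), character()), 0)
  expect_error(merge_long_short(c("A", "B"), c("B", "C")), "length class")
})

test_that("final lists intersect coefficient and summary gene sets", {
  expect_equal(intersect_final(c("A", "B", "C"), c("B", "C", "D")),
               c("B", "C"))
  expect_equal(intersect_final(c("A"), c("B")), character(0))
})

test_that("build_lists matches an end-to-end brute-force recomputation", {
  d <- generate_dataset(synthetic_config(n_genes = 20, seed = 44))
  fits <- fit_all_pairs(d$expression, d$methylation, d$phenotypes,
                        d$annotation)
  summaries <- summarize_genes(fits, d$annotation)
  L <- build_lists(summaries, fits)

  # scripted oracle: recompute every set from the raw fit table
  sz <- annotation_sizes(d$annotation)
  oracle_sets <- list(pos_long = character(), pos_short = character(),
                      neg_long = character(), neg_short = character())
  for (i in seq_len(nrow(sz))) {
    g <- sz$gene[i]
    f <- fits[fits$gene == g & fits$status == "ok", ]
    if (!nrow(f)) next
    long <- sz$m[i] > 2 || sz$n[i] > 20
    fr <- mean(f$beta1_p < 0.05)
    if (fr <= (if (long) 0.15 else 0.30)) next
    dir <- if (sum(f$beta1 > 0) > nrow(f) / 2) "pos"
      else if (sum(f$beta1 < 0) > nrow(f) / 2) "neg" else next
    key <- paste0(dir, if (long) "_long" else "_short")
    oracle_sets[[key]] <- c(oracle_sets[[key]], g)
  }
  for (nm in names(oracle_sets))
    expect_setequal(L[[nm]], oracle_sets[[nm]])

  ok <- fits$status == "ok"
  gt05 <- unique(fits$gene[ok & fits$beta1 > 0.5 & fits$beta1_p < 0.05])
  lt05 <- unique(fits$gene[ok & fits$beta1 < -0.5 & fits$beta1_p < 0.05])
  expect_setequal(L$pos_final,
                  intersect(gt05, union(oracle_sets$pos_long,
                                        oracle_sets$pos_short)))
  expect_setequal(L$neg_final,
                  intersect(lt05, union(oracle_sets$neg_long,
                                        oracle_sets$neg_short)))
  expect_setequal(L$all_final, union(L$pos_final, L$neg_final))

  # partition invariants
  expect_length(intersect(L$pos_final, L$neg_final), 0)
  expect_true(all(summaries$direction %in% c("positive", "negative", "none")))
  expect_true(all(L$filter_table$n_genes <= L$filter_table$n_pairs))
})
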