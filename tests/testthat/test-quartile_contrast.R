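test_that("extreme-group split floors the group size, excludes the middle and respects the ordering", {
  set.seed(21)
  for (n in c(8, 9, 120)) {
    m <- random_matrix(3, n)
    ord <- order_samples(m, full_signature(m))
    grp <- split_extremes(ord, 0.25)
    m_exp <- floor(0.25 * n)
    expect_length(grp$low, m_exp)
    expect_length(grp$high, m_exp)
    expect_length(intersect(grp$low, grp$high), 0)
    # every low-group score <= every high-group score (sorted-extremes oracle)
    sc <- setNames(ord$scores, ord$sample_ids)
    expect_true(max(sc[grp$low]) <= min(sc[grp$high]))
    # matches the brute-force oracle's sorted-extremes selection
    osort <- oracle_order(unclass(m))$sample_ids
    expect_identical(grp$low, osort[seq_len(m_exp)])
    expect_identical(grp$high, osort[seq.int(n - m_exp + 1L, n)])
  }
  # n = 9 at 25%: groups of floor(2.25) = 2, middle 5 excluded
  m9 <- random_matrix(3, 9)
  g9 <- split_extremes(order_samples(m9, full_signature(m9)), 0.25)
  expect_length(g9$low, 2); expect_length(g9$high, 2)

  # fraction = 0.5 partitions all samples (median split)
  m8 <- random_matrix(3, 8)
  g5 <- split_extremes(order_samples(m8, full_signature(m8)), 0.5)
  expect_setequal(c(g5$low, g5$high), colnames(m8))

  # a descending ordering still puts the lowest scores in `low`
  ord_d <- order_samples(m8, full_signature(m8), direction = "descending")
  g_d <- split_extremes(ord_d, 0.25)
  sc <- setNames(ord_d$scores, ord_d$sample_ids)
  expect_true(max(sc[g_d$low]) <= min(sc[g_d$high]))

  m4 <- random_matrix(3, 4)
  expect_error(split_extremes(order_samples(m4, full_signature(m4)), 0.25),
               "at least 2")
  expect_error(split_extremes(ord_d, 0.75), "fraction")
})

test_that("Welch statistic, df and p match stats::t.test to 1e-10 and obey swap symmetry", {
  set.seed(30)
  for (i in 1:25) {
    x <- rnorm(sample(3:40, 1), sd = runif(1, 0.3, 3))
    y <- rnorm(sample(3:40, 1), mean = runif(1, -1, 1),
               sd = runif(1, 0.3, 3))
    w <- welch_test(x, y)
    tt <- t.test(y, x, var.equal = FALSE)
    expect_equal(w$t, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(tt$parameter), tolerance = 1e-10)
    expect_equal(w$p, tt$p.value, tolerance = 1e-10)
    # Welch-Satterthwaite df bracket
    expect_gte(w$df, min(length(x), length(y)) - 1 - 1e-12)
    expect_lte(w$df, length(x) + length(y) - 2 + 1e-12)
    # swapping groups negates t, leaves df and p unchanged
    ws <- welch_test(y, x)
    expect_equal(ws$t, -w$t)
    expect_equal(ws$df, w$df)
    expect_equal(ws$p, w$p)
  }
})

test_that("degenerate Welch inputs resolve explicitly instead of erroring", {
  w0 <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w0$t, 0); expect_equal(w0$p, 1)
  expect_false(w0$degenerate)

  wc <- welch_test(c(2, 2, 2), c(2, 2, 2))  # both constant, equal
  expect_equal(wc$t, 0); expect_equal(wc$p, 1)

  wd <- welch_test(c(0, 0, 0, 0), c(1, 1, 1, 1))  # both constant, unequal
  expect_true(wd$degenerate)
  expect_equal(wd$p, .Machine$double.xmin)
  expect_true(is.infinite(wd$t) && wd$t > 0)

  expect_error(welch_test(1, c(1, 2)), "at least 2")
  # NA handling: pairwise deletion inside the test
  wna <- welch_test(c(1, 2, NA, 3), c(4, NA, 5, 6))
  expect_equal(wna$n_x, 3); expect_equal(wna$n_y, 3)
})

test_that("gene contrasts report direction, star tier and BH column per query gene", {
  co <- generate_cohort(cohort_spec(seed = 1))
  ord <- order_samples(co$matrix, wnt_signature())
  res <- contrast_genes(co$matrix, ord,
                        c("GLIS1", "CUX1", "CDH1", "OCLN", "NOT_A_GENE"))
  expect_equal(attr(res, "absent_genes"), "NOT_A_GENE")
  expect_equal(nrow(res), 4)
  up <- res[res$gene_id %in% c("GLIS1", "CUX1"), ]
  dn <- res[res$gene_id %in% c("CDH1", "OCLN"), ]
  expect_true(all(up$direction == "up"))
  expect_true(all(dn$direction == "down"))
  expect_true(all(res$p_value < 0.001))
  expect_true(all(res$tier == "***"))
  expect_true(all(res$n_low == 30 & res$n_high == 30))
  expect_equal(res$bh_fdr, p.adjust(res$p_value, "BH"))

  # a constant gene is flat with p = 1
  m <- unclass(co$matrix)
  m <- rbind(m, FLATGENE = rep(2.5, ncol(m)))
  resf <- contrast_genes(expr_matrix(m), ord, "FLATGENE")
  expect_equal(resf$direction, "flat")
  expect_equal(resf$p_value, 1)
  expect_equal(resf$tier, "ns")

  expect_error(contrast_genes(co$matrix, ord, "NOPE"), "none of the query")
})

test_that("tier thresholds follow the star convention", {
  expect_equal(significance_tier(c(0.2, 0.04, 0.009, 0.0009, 0.05)),
               c("ns", "*", "**", "***", "ns"))
  expect_error(significance_tier(0.1, tiers = c(0.01, 0.05, 0.001)),
               "decreasing")
})

test_that("Fisher combination matches the closed-form chi-square tail and its identities", {
  # k = 1 is the identity
  f1 <- fisher_combine(0.03)
  expect_equal(f1$p_combined, 0.03, tolerance = 1e-12)
  # all-ones null
  f0 <- fisher_combine(c(1, 1, 1))
  expect_equal(f0$chi2, 0); expect_equal(f0$p_combined, 1)
  # three tests at 0.05: chi2 = -6 ln 0.05, tail from an independent
  # closed-form oracle for 6 df
  f3 <- fisher_combine(c(0.05, 0.05, 0.05))
  expect_equal(f3$chi2, -6 * log(0.05), tolerance = 1e-12)
  expect_equal(f3$df, 6L)
  expect_equal(f3$p_combined, oracle_chisq6_tail(-6 * log(0.05)),
               tolerance = 1e-10)
  expect_error(fisher_combine(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(fisher_combine(c(0.5, 1.2)), "\\(0, 1\\]")
  expect_error(fisher_combine(numeric(0)), "at least one")
})

test_that("adding a p = 1 test never makes the Fisher combination more significant", {
  set.seed(55)
  for (i in 1:20) {
    ps <- runif(sample(1:5, 1))
    a <- fisher_combine(ps)
    b <- fisher_combine(c(ps, 1))
    expect_equal(b$chi2, a$chi2)
    expect_equal(b$df, a$df + 2L)
    expect_gte(b$p_combined, a$p_combined)
  }
})

test_that("concordance tallies count significant results in the expected direction", {
  df3 <- data.frame(dataset_id = c("Esserman", "Gluck", "TCGA"),
                    gene_id = "CUX1",
                    p_value = c(0.01, 0.001, 0.04),
                    direction = "up")
  t3 <- tally_concordance(df3, "up", alpha = 0.05)
  expect_equal(t3$n_datasets, 3); expect_equal(t3$n_concordant, 3)

  df8 <- data.frame(dataset_id = paste0("DS", 1:8), gene_id = "GLIS1",
                    p_value = c(rep(0.001, 7), 0.3),
                    direction = "up")
  t8 <- tally_concordance(df8, "up")
  expect_equal(t8$n_concordant, 7); expect_equal(t8$n_datasets, 8)

  # wrong direction is discordant even when significant
  dfw <- data.frame(dataset_id = "D", gene_id = "g", p_value = 0.001,
                    direction = "down")
  expect_equal(tally_concordance(dfw, "up")$n_concordant, 0)
  expect_error(tally_concordance(df8[0, ], "up"), "no per-dataset")
})

test_that("per-dataset contrasts combine gene-by-gene across cohorts", {
  specs <- lapply(1:3, function(s) cohort_spec(seed = s))
  tabs <- lapply(specs, function(sp) {
    co <- generate_cohort(sp)
    contrast_genes(co$matrix, order_samples(co$matrix, wnt_signature()),
                   c("GLIS1", "CDH1"))
  })
  names(tabs) <- paste0("DS", 1:3)
  comb <- combine_contrasts(tabs)
  expect_equal(sort(comb$gene_id), c("CDH1", "GLIS1"))
  expect_true(all(comb$k == 3))
  expect_true(all(comb$df == 6))
  g <- comb[comb$gene_id == "GLIS1", ]
  ps <- sapply(tabs, function(t) t$p_value[t$gene_id == "GLIS1"])
  expect_equal(g$chi2, -2 * sum(log(ps)), tolerance = 1e-12)
})
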