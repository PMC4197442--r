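test_that("cohort generation is deterministic and per-gene streams are independent", {
  sp <- cohort_spec(seed = 7)
  a <- generate_cohort(sp)
  b <- generate_cohort(sp)
  expect_identical(unclass(a$matrix), unclass(b$matrix))
  expect_identical(a$truth, b$truth)
  c2 <- generate_cohort(cohort_spec(seed = 8))
  expect_false(identical(unclass(a$matrix), unclass(c2$matrix)))
  # adding background genes leaves every existing gene's values untouched
  bigger <- generate_cohort(cohort_spec(seed = 7, n_background = 30L))
  shared <- rownames(a$matrix)
  expect_identical(unclass(a$matrix)[shared, ],
                   unclass(bigger$matrix)[shared, ])
})

test_that("invalid cohort specs are rejected before any sampling", {
  expect_error(cohort_spec(class_proportions = c(0.5, 0.5, 0.5)),
               "summing to 1")
  expect_error(cohort_spec(class_proportions = c(-0.2, 0.6, 0.6)),
               "non-negative|summing")
  expect_error(cohort_spec(noise_sd = 0), "noise_sd")
  expect_error(cohort_spec(missing_rate = 1), "missing_rate")
  expect_error(cohort_spec(n_samples = 3), "n_samples")
  expect_error(cohort_spec(emt_up_genes = c("VIM", "GLIS1")), "overlap")
})

test_that("the noiseless limit is ordered exactly and the default cohort nearly so", {
  co0 <- generate_cohort(cohort_spec(noise_sd = 1e-6, seed = 3))
  truth0 <- setNames(co0$truth$latent_score, co0$truth$sample_id)
  ord0 <- order_samples(co0$matrix, wnt_signature())
  expect_gte(ordering_concordance(ord0, truth0), 0.999)

  co <- generate_cohort(cohort_spec(seed = 3))
  truth <- setNames(co$truth$latent_score, co$truth$sample_id)
  expect_gte(ordering_concordance(order_samples(co$matrix, wnt_signature()),
                                  truth), 0.85)
})

test_that("missing-value masking and signature dropout behave as specified", {
  co <- generate_cohort(cohort_spec(missing_rate = 0.1, seed = 5))
  rate <- mean(is.na(unclass(co$matrix)))
  expect_gt(rate, 0.07); expect_lt(rate, 0.13)
  # ordering still works with missing entries (mid-rank imputation)
  expect_s3_class(order_samples(co$matrix, wnt_signature()),
                  "sample_ordering")

  drop5 <- generate_cohort(cohort_spec(
    dropout_genes = wnt_ligand_genes()[1:5], seed = 5))
  expect_false(any(wnt_ligand_genes()[1:5] %in% rownames(drop5$matrix)))
  expect_error(order_samples(drop5$matrix, wnt_signature()), "at least 15")
  # dropping 4 genes still leaves the cohort eligible
  drop4 <- generate_cohort(cohort_spec(
    dropout_genes = wnt_ligand_genes()[1:4], seed = 5))
  ord <- order_samples(drop4$matrix, wnt_signature())
  expect_equal(ord$n_missing_genes, 4L)
})

test_that("null cohorts are deterministic and carry no ordering signal", {
  a <- generate_null(50, 30, seed = 2)
  expect_identical(unclass(a), unclass(generate_null(50, 30, seed = 2)))
  expect_equal(dim(a), c(30L, 50L))
  expect_error(generate_null(3, 10), "n_samples")

  rho <- vapply(1:20, function(s) {
    m <- generate_null(100, 19, seed = s, gene_ids = wnt_ligand_genes())
    # arbitrary fixed per-sample covariate, keyed by sample id
    covariate <- setNames(seq_len(100), sprintf("S%03d", 1:100))
    ordering_concordance(order_samples(m, wnt_signature()), covariate)
  }, numeric(1))
  expect_true(all(abs(rho) < 0.3))
  expect_lt(abs(mean(rho)), 0.1)
})

test_that("null quartile contrasts reject at the nominal rate", {
  reps <- 2000
  p <- vapply(seq_len(reps), function(s) {
    m <- generate_null(40, 6, seed = 10000 + s,
                       gene_ids = c(sprintf("SIG%d", 1:5), "QUERY"))
    sig <- gene_signature(sprintf("SIG%d", 1:5))
    ord <- order_samples(m, sig)
    contrast_genes(m, ord, "QUERY")$p_value
  }, numeric(1))
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.04); expect_lte(rate, 0.06)
})

test_that("stronger signature effects yield monotonically better ordering recovery", {
  levels <- list(c(0, 0.3, 0.75), c(0, 1, 2.5), c(0, 3, 7.5))
  mean_conc <- vapply(levels, function(eff) {
    mean(vapply(1:20, function(s) {
      co <- generate_cohort(cohort_spec(signature_effects = eff, seed = s))
      ordering_concordance(
        order_samples(co$matrix, wnt_signature()),
        setNames(co$truth$latent_score, co$truth$sample_id))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_conc) > 0))
})

test_that("dataset panels mix eligibility failures with ground-truth reasons", {
  sig <- wnt_signature()
  panel <- make_dataset_panel(
    5,
    overrides = list(NULL, list(n_samples = 80L), NULL,
                     list(n_samples = 80L), NULL),
    seed = 1)
  screen <- filter_eligible(panel, sig)
  expect_equal(sum(screen$report$eligible), 3)
  expect_equal(length(screen$eligible), 3)
  expect_match(screen$report$reason[screen$report$dataset_id == "DS2"],
               "n=80 < 100")

  # a platform with only 14 signature genes is ineligible
  p14 <- make_dataset_panel(
    1, overrides = list(list(dropout_genes = wnt_ligand_genes()[1:5])),
    seed = 2)
  s14 <- filter_eligible(p14, sig)
  expect_false(s14$report$eligible)
  expect_match(s14$report$reason, "14/19")

  # no factor probe is ineligible even with a full signature
  pf <- make_dataset_panel(
    1, overrides = list(list(dropout_genes = c("CUX1", "GLIS1"))), seed = 3)
  sf <- filter_eligible(pf, sig)
  expect_false(sf$report$eligible)
  expect_match(sf$report$reason, "no probe")
})

test_that("a concordant 8-cohort panel tallies 8 of 8, and degrading one gives 7 of 8", {
  sig <- wnt_signature()
  tally_for <- function(panel) {
    contrasts <- lapply(panel, function(co)
      contrast_genes(co$matrix,
                     order_samples(co$matrix, sig), "GLIS1"))
    tally_concordance(contrasts, "up", alpha = 0.05, gene_id = "GLIS1")
  }
  full <- make_dataset_panel(8, seed = 11)
  t_full <- tally_for(full)
  expect_equal(t_full$n_datasets, 8)
  expect_equal(t_full$n_concordant, 8)

  degraded <- make_dataset_panel(
    8,
    overrides = c(rep(list(NULL), 7),
                  list(list(cofactor_effects = list(GLIS1 = c(0, 0, 0),
                                                    CUX1 = c(0, 0, 2))))),
    seed = 11)
  t_deg <- tally_for(degraded)
  expect_equal(t_deg$n_datasets, 8)
  expect_equal(t_deg$n_concordant, 7)
})
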