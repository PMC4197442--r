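#' Specify a synthetic expression cohort
#'
#' Describes the statistical structure the analysis pipeline assumes in real
#' tumor cohorts, so every stage can be validated against a known truth:
#' samples fall into three latent classes of low / medium / high signature
#' (Wnt) activity; a block of co-regulated transcription-factor genes
#' (GLIS1, CUX1) is elevated in the high class; a mesenchymal block (VIM,
#' CDH2, SNAI1, SNAI2, TWIST1) rises and an epithelial block (CDH1, OCLN)
#' falls with it. Expression is additive Gaussian on the log2 scale — the
#' standard approximation for normalized microarray intensities.
#'
#' Each sample also carries a continuous uniform intensity that spreads its
#' class's signature shift over `within_class_spread` log2 units, so the
#' cohort has a recoverable total order, not just a partition — the property
#' a rank-sum ordering is designed to exploit.
#'
#' @param n_samples Cohort size (default 120).
#' @param class_proportions Low/medium/high mixing proportions, summing
#'   to 1.
#' @param signature_genes Signature gene ids (default the 19 WNT ligands).
#' @param signature_effects Per-class mean shift of every signature gene, in
#'   log2 units (default 0 / +1 / +2.5).
#' @param within_class_spread Width of the within-class latent gradient in
#'   log2 units (default 0.5).
#' @param cofactor_effects Named list, gene id -> length-3 per-class shift
#'   (default GLIS1 and CUX1 at 0/0/+2).
#' @param emt_up_genes,emt_down_genes Mesenchymal / epithelial marker ids.
#' @param emt_up_shift,emt_down_shift High-class shift applied to those
#'   blocks (defaults +2 and -2 log2 units).
#' @param noise_sd Residual SD per measurement, log2 units (default 1).
#' @param gene_level_sd SD of per-gene baselines (default 1).
#' @param missing_rate Fraction of entries masked missing, in `[0, 1)`.
#' @param dropout_genes Genes removed from the emitted matrix (but kept in
#'   the truth record) — used to exercise the signature eligibility rule or
#'   to mimic a platform lacking a factor probe.
#' @param n_background Unstructured noise-only genes added for realism.
#' @param seed Integer RNG seed; identical spec + seed gives a bit-identical
#'   cohort.
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_samples = 120L,
                        class_proportions = c(low = 1/3, medium = 1/3,
                                              high = 1/3),
                        signature_genes = wnt_ligand_genes(),
                        signature_effects = c(low = 0, medium = 1,
                                              high = 2.5),
                        within_class_spread = 0.5,
                        cofactor_effects = list(GLIS1 = c(0, 0, 2),
                                                CUX1 = c(0, 0, 2)),
                        emt_up_genes = c("VIM", "CDH2", "SNAI1", "SNAI2",
                                         "TWIST1"),
                        emt_down_genes = c("CDH1", "OCLN"),
                        emt_up_shift = 2,
                        emt_down_shift = -2,
                        noise_sd = 1,
                        gene_level_sd = 1,
                        missing_rate = 0,
                        dropout_genes = character(),
                        n_background = 20L,
                        seed = 1L) {
  spec <- list(n_samples = as.integer(n_samples),
               class_proportions = class_proportions,
               signature_genes = signature_genes,
               signature_effects = signature_effects,
               within_class_spread = within_class_spread,
               cofactor_effects = cofactor_effects,
               emt_up_genes = emt_up_genes,
               emt_down_genes = emt_down_genes,
               emt_up_shift = emt_up_shift,
               emt_down_shift = emt_down_shift,
               noise_sd = noise_sd,
               gene_level_sd = gene_level_sd,
               missing_rate = missing_rate,
               dropout_genes = dropout_genes,
               n_background = as.integer(n_background),
               seed = as.integer(seed))
  validate_cohort_spec(spec)
  class(spec) <- "cohort_spec"
  spec
}

validate_cohort_spec <- function(spec) {
  p <- spec$class_proportions
  if (length(p) != 3L || any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("class_proportions must be 3 non-negative values summing to 1",
         call. = FALSE)
  if (spec$n_samples < 4L)
    stop("n_samples must be at least 4", call. = FALSE)
  if (!is.numeric(spec$noise_sd) || spec$noise_sd <= 0)
    stop("noise_sd must be positive", call. = FALSE)
  if (spec$missing_rate < 0 || spec$missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  if (length(spec$signature_effects) != 3L)
    stop("signature_effects must give one shift per class", call. = FALSE)
  if (!all(vapply(spec$cofactor_effects, length, 1L) == 3L))
    stop("each cofactor effect must give one shift per class",
         call. = FALSE)
  if (anyDuplicated(c(spec$signature_genes, names(spec$cofactor_effects),
                      spec$emt_up_genes, spec$emt_down_genes)))
    stop("gene families overlap; gene ids must be distinct across blocks",
         call. = FALSE)
  invisible(spec)
}

#' Generate a synthetic cohort from a spec
#'
#' Each entry is `gene baseline + class/latent effect + N(0, noise_sd)`.
#' Baselines are drawn once per gene from `N(0, gene_level_sd)`; each gene's
#' random draws use a stream seeded from the cohort seed and the gene name,
#' so adding genes to a spec never perturbs the values of existing genes.
#' Signature genes share the sample's latent shift
#' `signature_effects[class] + u * within_class_spread` with `u ~ U(0,1)`;
#' that shift is recorded as the sample's true latent score. Cofactor and
#' EMT genes receive fixed per-class shifts, so their planted contrast
#' effects are exact recovery targets.
#'
#' @param spec A [cohort_spec()].
#' @return List with `matrix` (an [expr_matrix()], dropout genes removed),
#'   `truth` (data.frame `sample_id`, `true_class`, `latent_score`) and
#'   `spec`.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  n <- spec$n_samples
  sample_ids <- sprintf("S%03d", seq_len(n))
  set.seed(spec$seed)
  cls <- sample(c("low", "medium", "high"), n, replace = TRUE,
                prob = spec$class_proportions)
  u <- stats::runif(n)
  cls_idx <- match(cls, c("low", "medium", "high"))
  latent <- unname(spec$signature_effects[cls_idx]) +
    u * spec$within_class_spread
  high_shift <- function(shift) c(0, 0, shift)[cls_idx]

  genes <- c(spec$signature_genes, names(spec$cofactor_effects),
             spec$emt_up_genes, spec$emt_down_genes,
             if (spec$n_background > 0L)
               sprintf("BG%03d", seq_len(spec$n_background)))
  vals <- base::matrix(NA_real_, length(genes), n,
                       dimnames = list(genes, sample_ids))
  for (g in genes) {
    shift <-
      if (g %in% spec$signature_genes) latent
      else if (g %in% names(spec$cofactor_effects))
        spec$cofactor_effects[[g]][cls_idx]
      else if (g %in% spec$emt_up_genes) high_shift(spec$emt_up_shift)
      else if (g %in% spec$emt_down_genes) high_shift(spec$emt_down_shift)
      else 0
    set.seed(gene_stream_seed(spec$seed, g))
    baseline <- stats::rnorm(1, 0, spec$gene_level_sd)
    vals[g, ] <- baseline + shift + stats::rnorm(n, 0, spec$noise_sd)
  }
  if (spec$missing_rate > 0) {
    set.seed(gene_stream_seed(spec$seed, ".missing_mask"))
    mask <- stats::runif(length(vals)) < spec$missing_rate
    vals[base::matrix(mask, nrow(vals))] <- NA_real_
  }
  emitted <- vals[setdiff(genes, spec$dropout_genes), , drop = FALSE]
  list(matrix = expr_matrix(emitted),
       truth = data.frame(sample_id = sample_ids, true_class = cls,
                          latent_score = latent,
                          stringsAsFactors = FALSE),
       spec = spec)
}

#' Generate a structureless null cohort
#'
#' All entries i.i.d. standard normal — no classes, no gradient — for
#' type-I-error and false-concordance checks.
#'
#' @param n_samples Number of samples (>= 4).
#' @param n_genes Number of genes (>= 1); rows are named `G0001`, ... unless
#'   `gene_ids` is given.
#' @param seed Integer RNG seed.
#' @param gene_ids Optional explicit gene ids of length `n_genes`.
#' @return An [expr_matrix()].
#' @export
generate_null <- function(n_samples, n_genes = 100L, seed = 1L,
                          gene_ids = NULL) {
  if (n_samples < 4L || n_genes < 1L)
    stop("need n_samples >= 4 and n_genes >= 1", call. = FALSE)
  if (is.null(gene_ids)) gene_ids <- sprintf("G%04d", seq_len(n_genes))
  if (length(gene_ids) != n_genes)
    stop("gene_ids length must equal n_genes", call. = FALSE)
  set.seed(as.integer(seed))
  expr_matrix(base::matrix(stats::rnorm(n_genes * n_samples),
                           n_genes, n_samples,
                           dimnames = list(gene_ids,
                                           sprintf("S%03d",
                                                   seq_len(n_samples)))))
}

#' Generate a panel of cohorts with mixed eligibility
#'
#' Emulates a public-database sweep: several independent cohorts, some of
#' which fail the eligibility screen (too few samples, too few signature
#' genes on the platform, no factor-gene probe). Per-dataset overrides are
#' lists of [cohort_spec()] arguments merged over the base spec; each
#' dataset gets its own deterministic sub-seed.
#'
#' @param n_datasets Number of cohorts (>= 1).
#' @param overrides List of per-dataset override lists; element `i` (if
#'   present and non-NULL) is merged into the base spec for dataset `i`.
#' @param base_spec Base [cohort_spec()].
#' @param seed Panel seed; dataset `i` uses `seed + 1009 * i`.
#' @return Named list of cohorts (`DS1`, `DS2`, ...), each as returned by
#'   [generate_cohort()] plus a `dataset_id` field.
#' @export
make_dataset_panel <- function(n_datasets, overrides = list(),
                               base_spec = cohort_spec(), seed = 1L) {
  if (n_datasets < 1L) stop("n_datasets must be >= 1", call. = FALSE)
  base <- unclass(base_spec)
  panel <- lapply(seq_len(n_datasets), function(i) {
    args <- base
    if (i <= length(overrides) && !is.null(overrides[[i]]))
      args <- utils::modifyList(args, overrides[[i]])
    args$seed <- as.integer(seed) + 1009L * i
    cohort <- generate_cohort(do.call(cohort_spec, args))
    cohort$dataset_id <- paste0("DS", i)
    cohort
  })
  names(panel) <- paste0("DS", seq_len(n_datasets))
  panel
}

#' Screen a panel of cohorts for eligibility
#'
#' A dataset is retained when it has at least `min_samples` samples, at
#' least `signature$min_present` of the signature genes, and a probe for at
#' least one of the factor genes — the screen used to select public breast
#' cancer datasets (100+ samples, >= 15 of the 19 Wnt ligands, a CUX1 or
#' GLIS1 probe).
#'
#' @param panel Named list of cohorts (as from [make_dataset_panel()]) or of
#'   bare [expr_matrix()] objects.
#' @param signature A [gene_signature()].
#' @param factor_genes At least one of these must be present (default CUX1,
#'   GLIS1). Use `character()` to waive the requirement.
#' @param min_samples Minimum cohort size (default 100).
#' @return List with `eligible` (the retained sub-list) and `report` (one
#'   row per dataset: sizes, counts, eligibility and reason).
#' @export
filter_eligible <- function(panel, signature,
                            factor_genes = c("CUX1", "GLIS1"),
                            min_samples = 100L) {
  get_mat <- function(x) if (inherits(x, "expr_matrix")) x else x$matrix
  rows <- lapply(names(panel), function(ds) {
    m <- get_mat(panel[[ds]])
    pres <- signature_presence(m, signature)
    has_factor <- length(factor_genes) == 0L ||
      any(factor_genes %in% rownames(m))
    ok_n <- ncol(m) >= min_samples
    reason <- c(if (!ok_n) sprintf("n=%d < %d", ncol(m), min_samples),
                if (!pres$eligible)
                  sprintf("%d/%d signature genes (need %d)",
                          length(pres$present), length(signature$genes),
                          signature$min_present),
                if (!has_factor)
                  paste0("no probe for ",
                         paste(factor_genes, collapse = "/")))
    data.frame(dataset_id = ds, n_samples = ncol(m),
               n_signature_present = length(pres$present),
               has_factor_probe = has_factor,
               eligible = ok_n && pres$eligible && has_factor,
               reason = if (length(reason))
                 paste(reason, collapse = "; ") else "",
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  list(eligible = panel[report$dataset_id[report$eligible]],
       report = report)
}
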