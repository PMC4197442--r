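#' @name pipeline
#' @title File-level pipeline steps
#'
#' @description
#' Orchestration wrappers that connect the computational core to files on
#' disk: each step reads plain-text inputs (or takes the in-memory objects
#' directly), runs one stage of the analysis, and writes TSV outputs whose
#' `#` header records the package version, a config fingerprint and the
#' seed, so every result file is traceable to the run that made it. The
#' numbered drivers under `analysis/` are thin scripts over these.
NULL

as_expr_matrix <- function(x, ...) {
  if (inherits(x, "expr_matrix")) x
  else if (is.character(x) && length(x) == 1L) read_matrix(x, ...)
  else expr_matrix(x)
}

as_signature <- function(x) {
  if (inherits(x, "gene_signature")) x else read_signature(x)
}

#' Order a cohort by a signature and write the ordering
#'
#' @param matrix An [expr_matrix()] or path to a matrix TSV.
#' @param signature A [gene_signature()] or path to a signature file.
#' @param out Output TSV path (optional; no file written when NULL).
#' @param direction Sort direction, see [order_samples()].
#' @return The `sample_ordering`, invisibly when `out` is given.
#' @export
run_order <- function(matrix, signature, out = NULL,
                      direction = "ascending") {
  m <- as_expr_matrix(matrix)
  sig <- as_signature(signature)
  ord <- order_samples(m, sig, direction)
  if (!is.null(out)) {
    write_ordering(ord, out,
                   extra_header = provenance_header(
                     list(signature = sig$name, direction = direction)))
    return(invisible(ord))
  }
  ord
}

#' Contrast query genes over the extreme quantiles of one or more cohorts
#'
#' For each cohort: order by the signature, split off the extreme
#' `fraction` groups, and Welch-test every query gene. With more than one
#' cohort the per-gene p-values are additionally combined across cohorts by
#' Fisher's method.
#'
#' @param matrices Named list of matrices (objects or paths). A single
#'   matrix may be passed bare.
#' @param signature Signature object or path.
#' @param query_genes Genes to contrast (e.g. factors + EMT markers).
#' @param fraction Extreme-group fraction (default 0.25).
#' @param tiers Significance thresholds for the star tiers.
#' @param out_dir Output directory (optional). Writes
#'   `contrast_<dataset>.tsv` per cohort and `combined.tsv` when more than
#'   one cohort is given.
#' @return List with `contrasts` (named list of data.frames) and `combined`
#'   (data.frame or NULL for a single cohort).
#' @export
run_contrast <- function(matrices, signature, query_genes, fraction = 0.25,
                         tiers = c(0.05, 0.01, 0.001), out_dir = NULL) {
  if (!is.list(matrices) || inherits(matrices, "expr_matrix"))
    matrices <- list(dataset = matrices)
  if (is.null(names(matrices)))
    names(matrices) <- paste0("DS", seq_along(matrices))
  sig <- as_signature(signature)
  contrasts <- lapply(matrices, function(x) {
    m <- as_expr_matrix(x)
    contrast_genes(m, order_samples(m, sig), query_genes,
                   fraction = fraction, tiers = tiers)
  })
  combined <- if (length(contrasts) > 1L) combine_contrasts(contrasts)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- provenance_header(list(signature = sig$name,
                                  fraction = fraction, tiers = tiers))
    for (ds in names(contrasts))
      write_contrast(contrasts[[ds]],
                     file.path(out_dir, paste0("contrast_", ds, ".tsv")),
                     extra_header = hdr)
    if (!is.null(combined))
      write_contrast(combined, file.path(out_dir, "combined.tsv"),
                     extra_header = hdr)
  }
  list(contrasts = contrasts, combined = combined)
}

#' Cluster a cohort over a signature and write tree + heatmap tables
#'
#' Runs [cluster_samples()], cuts the tree at `k`, and exports two
#' heatmap-ready tables over the signature plus annotation genes: one in
#' dendrogram leaf order and one in rank-sum (BreSAT) order.
#'
#' @param matrix Matrix object or path.
#' @param signature Signature object or path.
#' @param k Number of clusters to cut (default 3: the low / medium / high
#'   signature-activity split).
#' @param annotation_genes Extra genes displayed below the signature block.
#' @param distance,linkage,standardize See [cluster_samples()].
#' @param row_scaling Display scaling for the heatmap tables.
#' @param out_dir Output directory (optional): `tree.nwk`, `clusters.tsv`,
#'   `heatmap_cluster_order.tsv`, `heatmap_bresat_order.tsv` (+ YAML
#'   sidecars).
#' @return List with `tree`, `clusters`, `ordering`, `heatmap_cluster`,
#'   `heatmap_bresat`.
#' @export
run_cluster <- function(matrix, signature, k = 3L,
                        annotation_genes = character(),
                        distance = "euclidean", linkage = "ward.D2",
                        standardize = TRUE,
                        row_scaling = c("zscore", "none"), out_dir = NULL) {
  row_scaling <- match.arg(row_scaling)
  m <- as_expr_matrix(matrix)
  sig <- as_signature(signature)
  tree <- cluster_samples(m, sig, distance = distance, linkage = linkage,
                          standardize = standardize)
  clusters <- cut_clusters(tree, k)
  ord <- order_samples(m, sig)
  rows <- c(sig$genes, annotation_genes)
  hm_cluster <- export_heatmap_table(m, rows, tree$leaf_order, row_scaling)
  hm_bresat <- export_heatmap_table(m, rows, ord$sample_ids, row_scaling)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    params <- list(distance = distance, linkage = linkage,
                   standardize = standardize, k = as.integer(k),
                   signature = sig$name)
    writeLines(cluster_newick(tree), file.path(out_dir, "tree.nwk"))
    utils::write.table(
      data.frame(sample_id = names(clusters), cluster = unname(clusters)),
      file.path(out_dir, "clusters.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    write_heatmap_table(hm_cluster,
                        file.path(out_dir, "heatmap_cluster_order.tsv"),
                        params)
    write_heatmap_table(hm_bresat,
                        file.path(out_dir, "heatmap_bresat_order.tsv"),
                        params)
  }
  list(tree = tree, clusters = clusters, ordering = ord,
       heatmap_cluster = hm_cluster, heatmap_bresat = hm_bresat)
}

#' Simulate a cohort and write it to disk
#'
#' @param spec A [cohort_spec()] (or list of arguments for one).
#' @param out_dir Output directory: `matrix.tsv`, `truth.tsv`, `spec.yaml`.
#' @return The generated cohort (list with `matrix`, `truth`, `spec`),
#'   invisibly when written.
#' @export
run_simulate <- function(spec = cohort_spec(), out_dir = NULL) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  cohort <- generate_cohort(spec)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_matrix(cohort$matrix, file.path(out_dir, "matrix.tsv"))
    utils::write.table(cohort$truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    yaml::write_yaml(
      lapply(unclass(spec), function(x)
        if (is.numeric(x) || is.character(x)) as.vector(x) else x),
      file.path(out_dir, "spec.yaml"))
    return(invisible(cohort))
  }
  cohort
}

#' Meta-analysis over a panel of cohorts
#'
#' The full cross-dataset workflow: screen every cohort for eligibility
#' (sample floor, signature coverage, factor probe), run the extreme-
#' quantile contrast on each eligible cohort, and tally per-gene
#' concordance — how many of the eligible datasets show each query gene
#' significant in its expected direction.
#'
#' @param panel Named list of cohorts ([make_dataset_panel()] output,
#'   matrices, or paths).
#' @param signature Signature object or path.
#' @param query data.frame with columns `gene_id` and `expected_direction`
#'   (`"up"`/`"down"`).
#' @param fraction Extreme-group fraction (default 0.25).
#' @param alpha Concordance significance level (default 0.05).
#' @param factor_genes,min_samples Eligibility screen parameters, see
#'   [filter_eligible()].
#' @param out_dir Output directory (optional): `eligibility.tsv`,
#'   per-dataset contrast TSVs, `tally.tsv`.
#' @return List with `eligibility` (report data.frame), `contrasts` (per
#'   eligible dataset), `tally` (data.frame `gene_id`, `expected_direction`,
#'   `n_datasets`, `n_concordant`).
#' @export
run_meta <- function(panel, signature, query, fraction = 0.25,
                     alpha = 0.05, factor_genes = c("CUX1", "GLIS1"),
                     min_samples = 100L, out_dir = NULL) {
  sig <- as_signature(signature)
  panel <- lapply(panel, function(x)
    if (is.list(x) && !is.null(x$matrix)) x else as_expr_matrix(x))
  screen <- filter_eligible(panel, sig, factor_genes = factor_genes,
                            min_samples = min_samples)
  if (length(screen$eligible) == 0L)
    stop("no eligible datasets in the panel:\n",
         paste(screen$report$dataset_id, screen$report$reason,
               sep = ": ", collapse = "\n"), call. = FALSE)
  contrasts <- lapply(screen$eligible, function(x) {
    m <- if (inherits(x, "expr_matrix")) x else x$matrix
    present <- intersect(query$gene_id, rownames(m))
    contrast_genes(m, order_samples(m, sig), present, fraction = fraction)
  })
  tally <- do.call(rbind, lapply(seq_len(nrow(query)), function(i) {
    tl <- tally_concordance(contrasts,
                            expected_direction = query$expected_direction[i],
                            alpha = alpha, gene_id = query$gene_id[i])
    data.frame(gene_id = tl$gene_id,
               expected_direction = query$expected_direction[i],
               n_datasets = tl$n_datasets,
               n_concordant = tl$n_concordant,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- provenance_header(list(signature = sig$name, fraction = fraction,
                                  alpha = alpha, min_samples = min_samples))
    utils::write.table(screen$report, file.path(out_dir, "eligibility.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (ds in names(contrasts))
      write_contrast(contrasts[[ds]],
                     file.path(out_dir, paste0("contrast_", ds, ".tsv")),
                     extra_header = hdr)
    con <- file(file.path(out_dir, "tally.tsv"), "w")
    writeLines(hdr, con)
    utils::write.table(tally, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }
  list(eligibility = screen$report, contrasts = contrasts, tally = tally)
}
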