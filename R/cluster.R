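#' Unsupervised hierarchical clustering of samples over a signature
#'
#' Agglomerative clustering of samples using only the signature-gene rows —
#' the procedure that, applied to a tumor cohort over the Wnt ligand genes,
#' splits it into low / medium / high signature-expression groups. By
#' default each gene row is standardized (z-scored) before computing
#' Euclidean distances between samples, so every gene contributes on a
#' common scale regardless of its baseline; linkage defaults to Ward's
#' minimum-variance criterion (`"ward.D2"`), which recovers compact
#' Gaussian-like expression classes more reliably than average linkage
#' (average linkage tends to chain and to shear off singletons at realistic
#' noise levels). Both choices are configurable and are recorded on the
#' returned object and in every written output.
#'
#' @param matrix An [expr_matrix()].
#' @param signature A [gene_signature()]; the eligibility rule of
#'   [signature_presence()] applies.
#' @param distance Distance metric passed to [stats::dist()]
#'   (default `"euclidean"`).
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (default `"ward.D2"`).
#' @param standardize Z-score each gene row before distances (default TRUE).
#'   Constant rows are left unscaled.
#' @return A `cluster_tree`: list wrapping the `hclust` object plus
#'   `leaf_order` (sample ids in dendrogram order) and the parameters used.
#' @export
cluster_samples <- function(matrix, signature, distance = "euclidean",
                            linkage = "ward.D2", standardize = TRUE) {
  pres <- require_eligible(matrix, signature)
  if (ncol(matrix) < 3L)
    stop("clustering needs at least 3 samples", call. = FALSE)
  sub <- matrix[pres$present, , drop = FALSE]
  if (standardize) sub <- zscore_rows(sub)
  d <- stats::dist(t(sub), method = distance)
  hc <- stats::hclust(d, method = linkage)
  structure(list(hclust = hc,
                 leaf_order = hc$labels[hc$order],
                 genes_used = pres$present,
                 distance = distance, linkage = linkage,
                 standardize = standardize),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf(
    "cluster_tree: %d samples over %d genes (%s distance, %s linkage%s)\n",
    length(x$leaf_order), length(x$genes_used), x$distance, x$linkage,
    if (x$standardize) ", z-scored rows" else ""))
  invisible(x)
}

#' Cut a cluster tree into k groups
#'
#' @param tree A `cluster_tree` from [cluster_samples()].
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Named integer vector mapping sample id to cluster label. Labels
#'   are arbitrary but deterministic given the tree.
#' @export
cut_clusters <- function(tree, k) {
  n <- length(tree$leaf_order)
  if (!is.numeric(k) || k < 1 || k > n)
    stop("k must lie in [1, ", n, "]", call. = FALSE)
  stats::cutree(tree$hclust, k = k)
}

#' Export a cluster tree as a Newick string
#'
#' Sample ids become leaves, merge heights branch lengths.
#'
#' @param tree A `cluster_tree`.
#' @return Single Newick string.
#' @export
cluster_newick <- function(tree) {
  ape::write.tree(ape::as.phylo(tree$hclust))
}

zscore_rows <- function(values) {
  out <- values
  flagged <- character()
  for (i in seq_len(nrow(values))) {
    v <- values[i, ]
    s <- stats::sd(v, na.rm = TRUE)
    if (is.na(s) || s == 0) {
      flagged <- c(flagged, rownames(values)[i])
    } else {
      out[i, ] <- (v - mean(v, na.rm = TRUE)) / s
    }
  }
  attr(out, "constant_rows") <- flagged
  out
}

#' Build a heatmap-ready ordered expression table
#'
#' Subsets the requested gene rows and reorders the sample columns — either
#' in dendrogram leaf order or in rank-sum (BreSAT) order — for display.
#' Row z-scaling is display-layer only and never feeds back into any
#' statistic; constant rows are flagged in the `constant_rows` attribute and
#' left unscaled. The usual layout puts the signature block first and the
#' annotation genes (CUX1, GLIS1, the EMT markers) below it, which is simply
#' the concatenation order of `row_genes`.
#'
#' @param matrix An [expr_matrix()].
#' @param row_genes Genes to include, top to bottom; absent genes are
#'   reported in the `absent_genes` attribute and skipped.
#' @param column_order Sample id sequence; must be a permutation of the
#'   matrix samples (e.g. `ordering$sample_ids` or `tree$leaf_order`).
#' @param row_scaling `"none"` or `"zscore"`.
#' @return Numeric matrix, rows in `row_genes` order, columns in
#'   `column_order`.
#' @export
export_heatmap_table <- function(matrix, row_genes, column_order,
                                 row_scaling = c("none", "zscore")) {
  row_scaling <- match.arg(row_scaling)
  if (length(column_order) != ncol(matrix) ||
      !setequal(column_order, colnames(matrix)) ||
      anyDuplicated(column_order))
    stop("column_order must be a permutation of the matrix samples",
         call. = FALSE)
  absent <- setdiff(row_genes, rownames(matrix))
  genes <- intersect(row_genes, rownames(matrix))
  if (length(genes) == 0L)
    stop("none of the requested genes are present", call. = FALSE)
  out <- unclass(matrix)[genes, column_order, drop = FALSE]
  if (row_scaling == "zscore") out <- zscore_rows(out)
  attr(out, "absent_genes") <- absent
  attr(out, "row_scaling") <- row_scaling
  out
}

#' Write a heatmap table with a YAML sidecar
#'
#' TSV whose first row holds the ordered sample ids; the sidecar
#' (`<path>.yaml`) records distance, linkage, scaling and k so a figure can
#' be reproduced exactly.
#'
#' @param table Matrix from [export_heatmap_table()].
#' @param path Output TSV path.
#' @param params Named list written to the sidecar.
#' @export
write_heatmap_table <- function(table, path, params = list()) {
  df <- data.frame(gene_id = rownames(table), table,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  params$row_scaling <- attr(table, "row_scaling")
  params$constant_rows <- as.list(attr(table, "constant_rows"))
  params$absent_genes <- as.list(attr(table, "absent_genes"))
  yaml::write_yaml(params, paste0(path, ".yaml"))
  invisible(path)
}
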