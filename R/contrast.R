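#' Split an ordering into its extreme quantile groups
#'
#' Returns the lowest- and highest-scoring `floor(fraction * n)` samples of a
#' rank-sum ordering — the "bottom 25% vs top 25%" contrast groups when
#' `fraction = 0.25`. Flooring guarantees the two groups are disjoint and
#' equal-sized for any n; the middle samples are excluded.
#'
#' @param ordering A `sample_ordering` from [order_samples()].
#' @param fraction Fraction of samples per group, in `(0, 0.5]`.
#' @return List with character vectors `low` and `high` (sample ids).
#' @export
split_extremes <- function(ordering, fraction = 0.25) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 0.5)
    stop("fraction must lie in (0, 0.5]", call. = FALSE)
  ids <- ordering$sample_ids
  if (ordering$direction == "descending") ids <- rev(ids)
  n <- length(ids)
  m <- floor(fraction * n)
  if (m < 2L)
    stop("extreme groups would have ", m,
         " samples; need at least 2 per group (n = ", n, ")",
         call. = FALSE)
  list(low = ids[seq_len(m)], high = ids[seq.int(n - m + 1L, n)])
}

#' Welch-corrected two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value. The statistic is oriented as `mean(y) - mean(x)`,
#' so with `x` the low group and `y` the high group a positive `t` means the
#' gene is higher in the high group.
#'
#' Degenerate inputs that a stock t-test refuses are resolved explicitly:
#' if both groups are constant and equal, `t = 0`, `p = 1`; if both are
#' constant but unequal, the difference is infinitely significant at this
#' noise model, reported as the smallest representable positive p with
#' `degenerate = TRUE`.
#'
#' @param x,y Numeric vectors, each of length >= 2; `NA`s are dropped.
#' @return List with `t`, `df`, `p`, `mean_x`, `mean_y`, `n_x`, `n_y`,
#'   `degenerate`.
#' @export
welch_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L)
    stop("welch_test needs at least 2 observations per group (got ",
         nx, " and ", ny, ")", call. = FALSE)
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)   # n-1 denominator
  se2 <- vx / nx + vy / ny
  if (se2 == 0) {
    if (mx == my)
      return(list(t = 0, df = nx + ny - 2, p = 1, mean_x = mx, mean_y = my,
                  n_x = nx, n_y = ny, degenerate = FALSE))
    return(list(t = sign(my - mx) * Inf, df = nx + ny - 2,
                p = .Machine$double.xmin, mean_x = mx, mean_y = my,
                n_x = nx, n_y = ny, degenerate = TRUE))
  }
  t <- (my - mx) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  list(t = t, df = df, p = p, mean_x = mx, mean_y = my,
       n_x = nx, n_y = ny, degenerate = FALSE)
}

#' Significance tier for a p-value
#'
#' Star notation used throughout the reports: `***` for p < 0.001, `**` for
#' p < 0.01, `*` for p < 0.05, `ns` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @param tiers Strictly decreasing thresholds.
#' @return Character vector of tiers.
#' @export
significance_tier <- function(p, tiers = c(0.05, 0.01, 0.001)) {
  if (is.unsorted(rev(tiers), strictly = TRUE))
    stop("tiers must be strictly decreasing", call. = FALSE)
  stars <- vapply(p, function(pp) sum(pp < tiers), integer(1))
  ifelse(stars == 0L, "ns", strrep("*", stars))
}

#' Contrast query genes between extreme quantile groups
#'
#' For each query gene present in the matrix, compares its expression between
#' the bottom and top `fraction` of the signature ordering with
#' [welch_test()]. Samples missing a value for a gene are dropped from that
#' gene's contrast only (pairwise deletion). A Benjamini-Hochberg FDR column
#' over the query set is reported as supplementary output; the star tiers
#' are the raw per-gene Welch p-values, uncorrected.
#'
#' @param matrix An [expr_matrix()].
#' @param ordering A `sample_ordering` over the same samples.
#' @param query_genes Character vector of genes to test; absent genes are
#'   reported in the `absent_genes` attribute and skipped.
#' @param fraction Per-group fraction, see [split_extremes()].
#' @param tiers Significance thresholds, see [significance_tier()].
#' @return data.frame with one row per present query gene: `gene_id`,
#'   `n_low`, `n_high`, `mean_low`, `mean_high`, `t_stat`, `df`, `p_value`,
#'   `direction` (up/down/flat for the high vs low group), `tier`, `bh_fdr`.
#' @export
contrast_genes <- function(matrix, ordering, query_genes, fraction = 0.25,
                           tiers = c(0.05, 0.01, 0.001)) {
  absent <- setdiff(query_genes, rownames(matrix))
  genes <- intersect(query_genes, rownames(matrix))
  if (length(genes) == 0L)
    stop("none of the query genes are present in the matrix: ",
         paste(query_genes, collapse = ", "), call. = FALSE)
  grp <- split_extremes(ordering, fraction)
  rows <- lapply(genes, function(g) {
    w <- welch_test(matrix[g, grp$low], matrix[g, grp$high])
    d <- w$mean_y - w$mean_x
    data.frame(gene_id = g, n_low = w$n_x, n_high = w$n_y,
               mean_low = w$mean_x, mean_high = w$mean_y,
               t_stat = w$t, df = w$df, p_value = w$p,
               direction = if (d > 0) "up" else if (d < 0) "down" else "flat",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$tier <- significance_tier(out$p_value, tiers)
  out$bh_fdr <- stats::p.adjust(out$p_value, method = "BH")
  attr(out, "absent_genes") <- absent
  out
}

#' Combine independent p-values by Fisher's method
#'
#' The statistic `-2 * sum(log(p_i))` over k independent tests is referred to
#' a chi-square distribution with `2k` degrees of freedom. With k = 1 the
#' combination is the identity.
#'
#' @param p_values Numeric vector of p-values in `(0, 1]`, length >= 1.
#' @return List with `k`, `chi2`, `df`, `p_combined`.
#' @export
fisher_combine <- function(p_values) {
  if (length(p_values) < 1L)
    stop("fisher_combine needs at least one p-value", call. = FALSE)
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  k <- length(p_values)
  chi2 <- -2 * sum(log(p_values))
  list(k = k, chi2 = chi2, df = 2L * k,
       p_combined = stats::pchisq(chi2, df = 2 * k, lower.tail = FALSE))
}

#' Combine per-dataset contrasts gene by gene
#'
#' Applies [fisher_combine()] to each gene's Welch p-values across a list of
#' per-dataset contrast tables (as from [contrast_genes()]); only genes
#' tested in at least one dataset appear.
#'
#' @param contrast_list Named list of contrast data.frames, one per dataset.
#' @return data.frame with `gene_id`, `k`, `chi2`, `df`, `p_combined`.
#' @export
combine_contrasts <- function(contrast_list) {
  if (length(contrast_list) < 1L)
    stop("no contrast tables supplied", call. = FALSE)
  all_genes <- unique(unlist(lapply(contrast_list, `[[`, "gene_id")))
  rows <- lapply(all_genes, function(g) {
    ps <- unlist(lapply(contrast_list, function(df)
      df$p_value[df$gene_id == g]))
    fc <- fisher_combine(ps)
    data.frame(gene_id = g, k = fc$k, chi2 = fc$chi2, df = fc$df,
               p_combined = fc$p_combined, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Tally cross-dataset concordance for one gene
#'
#' The "x out of y datasets" report: a dataset is concordant for a gene when
#' that gene's contrast is significant at `alpha` *and* in the expected
#' direction.
#'
#' @param per_dataset_results data.frame with columns `dataset_id`,
#'   `p_value`, `direction` (one row per dataset for the gene under tally),
#'   or a named list of [contrast_genes()] tables from which the `gene_id`
#'   rows are pulled.
#' @param expected_direction `"up"` or `"down"`.
#' @param alpha Significance level, default 0.05.
#' @param gene_id Required when a list of contrast tables is supplied.
#' @return List with `gene_id`, `n_datasets`, `n_concordant`.
#' @export
tally_concordance <- function(per_dataset_results,
                              expected_direction = c("up", "down"),
                              alpha = 0.05, gene_id = NULL) {
  expected_direction <- match.arg(expected_direction)
  if (is.data.frame(per_dataset_results)) {
    df <- per_dataset_results
    if (is.null(gene_id)) gene_id <- unique(df$gene_id)[1L]
  } else {
    if (is.null(gene_id))
      stop("gene_id is required when passing a list of contrast tables",
           call. = FALSE)
    rows <- lapply(names(per_dataset_results), function(ds) {
      tab <- per_dataset_results[[ds]]
      hit <- tab[tab$gene_id == gene_id, , drop = FALSE]
      if (nrow(hit)) cbind(dataset_id = ds, hit) else NULL
    })
    df <- do.call(rbind, rows)
  }
  if (is.null(df) || nrow(df) == 0L)
    stop("no per-dataset results to tally", call. = FALSE)
  conc <- df$p_value < alpha & df$direction == expected_direction
  list(gene_id = gene_id, n_datasets = nrow(df),
       n_concordant = sum(conc))
}

#' Write a contrast table as TSV
#'
#' @param contrast data.frame from [contrast_genes()] (or the combined table
#'   from [combine_contrasts()]).
#' @param path Output path.
#' @param extra_header Optional `#` provenance lines.
#' @export
write_contrast <- function(contrast, path, extra_header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(extra_header)) writeLines(extra_header, con)
  absent <- attr(contrast, "absent_genes")
  if (length(absent))
    writeLines(paste0("# absent_genes=", paste(absent, collapse = ",")), con)
  utils::write.table(contrast, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
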