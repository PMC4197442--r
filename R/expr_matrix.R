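#' Construct an expression matrix
#'
#' An `expr_matrix` is a plain numeric matrix of log-scale expression values
#' with unique gene identifiers as row names and unique sample identifiers as
#' column names. Missing measurements are `NA`. Values are assumed to be
#' already normalized and on a log scale; no preprocessing is performed by
#' this package.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row and
#'   column names are required and must be unique.
#' @return The validated matrix with class `expr_matrix` prepended.
#' @export
expr_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) < 1L || ncol(values) < 2L)
    stop("expression matrix needs at least 1 gene and 2 samples, got ",
         nrow(values), " x ", ncol(values), call. = FALSE)
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("`values` must have gene row names and sample column names",
         call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  class(values) <- c("expr_matrix", class(values))
  values
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%d missing entries)\n",
              nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

#' Collapse duplicated probe rows to one row per gene
#'
#' Microarray matrices often carry several probes per gene. Rows sharing a
#' gene identifier are merged per sample with the chosen policy. Collapsing
#' an already-unique matrix is a no-op (row order of first occurrence is
#' kept). `NA` entries are ignored unless a gene/sample cell has no observed
#' probe at all, in which case it stays `NA`.
#'
#' @param values Numeric matrix with (possibly duplicated) gene row names.
#' @param collapse One of `"max"`, `"mean"`, `"median"`. The default `"max"`
#'   keeps, per sample, the strongest probe signal, which preserves detection
#'   of an expressed isoform.
#' @return Numeric matrix with unique row names.
#' @export
collapse_probes <- function(values, collapse = c("max", "mean", "median")) {
  collapse <- match.arg(collapse)
  gene_ids <- rownames(values)
  if (!anyDuplicated(gene_ids)) return(values)
  fun <- switch(collapse,
    max = function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE),
    mean = function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE),
    median = function(v) if (all(is.na(v))) NA_real_ else
      stats::median(v, na.rm = TRUE))
  keep <- unique(gene_ids)
  out <- matrix(NA_real_, length(keep), ncol(values),
                dimnames = list(keep, colnames(values)))
  for (g in keep) {
    rows <- values[gene_ids == g, , drop = FALSE]
    out[g, ] <- if (nrow(rows) == 1L) rows[1L, ] else apply(rows, 2L, fun)
  }
  out
}

#' Read a tab-delimited expression matrix
#'
#' Expects a UTF-8 TSV with a header row: one gene-identifier column (first
#' by default) and one numeric column per sample. Empty cells and `NA` are
#' read as missing. Sample order in the file is preserved. Duplicate gene
#' rows are collapsed with [collapse_probes()].
#'
#' @param path File path.
#' @param gene_column Name of the gene-identifier column; default is the
#'   first column of the file.
#' @param collapse Probe-collapse policy, see [collapse_probes()].
#' @return An [expr_matrix()].
#' @export
read_matrix <- function(path, gene_column = NULL,
                        collapse = c("max", "mean", "median")) {
  collapse <- match.arg(collapse)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L)
    stop("malformed header in ", path,
         ": need a gene column plus at least one sample column",
         call. = FALSE)
  if (anyDuplicated(header))
    stop("malformed header in ", path, ": duplicated column names",
         call. = FALSE)
  if (is.null(gene_column)) gene_column <- header[1L]
  if (!gene_column %in% header)
    stop("gene column '", gene_column, "' not found in ", path,
         call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character",
                          na.strings = c("", "NA"))
  sample_cols <- setdiff(names(df), gene_column)
  if (length(sample_cols) < 1L)
    stop("zero sample columns in ", path, call. = FALSE)
  vals <- matrix(NA_real_, nrow(df), length(sample_cols),
                 dimnames = list(NULL, sample_cols))
  for (j in seq_along(sample_cols)) {
    raw <- df[[sample_cols[j]]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad))
      stop("non-numeric value '", raw[bad[1L]], "' at row ", bad[1L],
           ", column '", sample_cols[j], "' in ", path, call. = FALSE)
    vals[, j] <- num
  }
  rownames(vals) <- df[[gene_column]]
  expr_matrix(collapse_probes(vals, collapse))
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_matrix()]: first column holds gene identifiers, remaining
#' columns the samples in matrix order. Missing entries are written as empty
#' fields. Numbers carry 15 significant digits so a round trip reproduces the
#' matrix to within double-precision formatting.
#'
#' @param matrix An [expr_matrix()] (or matrix with valid dimnames).
#' @param path Output file path.
#' @param gene_column Header for the gene-identifier column.
#' @export
write_matrix <- function(matrix, path, gene_column = "gene_id") {
  matrix <- expr_matrix(unclass(matrix))  # validate before touching disk
  fmt <- format(matrix, digits = 15, trim = TRUE)
  fmt[is.na(matrix)] <- ""
  lines <- c(paste(c(gene_column, colnames(matrix)), collapse = "\t"),
             paste(rownames(matrix),
                   apply(fmt, 1L, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample-annotation table
#'
#' TSV with a `sample_id` column plus arbitrary attribute columns (histology,
#' transgene, true simulated class, ...). When `matrix` is supplied, every
#' annotated sample must exist in it.
#'
#' @param path File path.
#' @param matrix Optional companion [expr_matrix()] to validate against.
#' @return A data.frame with character columns.
#' @export
read_annotation <- function(path, matrix = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  if (!"sample_id" %in% names(df))
    stop("annotation file lacks a 'sample_id' column: ", path,
         call. = FALSE)
  if (!is.null(matrix)) {
    unknown <- setdiff(df$sample_id, colnames(matrix))
    if (length(unknown))
      stop("annotated samples absent from matrix: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  df
}
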