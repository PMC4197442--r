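#' Construct a gene signature
#'
#' A signature is a named, ordered set of gene identifiers that defines the
#' ordering axis (for example the 19 WNT ligand genes), together with
#' `min_present`, the smallest number of signature genes that must be found
#' in a matrix for the dataset to be eligible. The Wnt-ligand signature
#' shipped with the package uses `min_present = 15` — the "at least 15 of
#' the 19 ligands" eligibility rule.
#'
#' @param genes Character vector of gene identifiers, non-empty, no
#'   duplicates.
#' @param name Signature label.
#' @param min_present Integer in `[1, length(genes)]`; defaults to requiring
#'   every gene.
#' @return An object of class `gene_signature`.
#' @export
gene_signature <- function(genes, name = "signature",
                           min_present = length(genes)) {
  genes <- as.character(genes)
  if (length(genes) < 1L) stop("signature has no genes", call. = FALSE)
  if (anyDuplicated(genes))
    stop("duplicate signature genes: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  min_present <- as.integer(min_present)
  if (is.na(min_present) || min_present < 1L || min_present > length(genes))
    stop("min_present must lie in [1, ", length(genes), "]", call. = FALSE)
  structure(list(name = name, genes = genes, min_present = min_present),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature '%s': %d genes, min_present = %d\n",
              x$name, length(x$genes), x$min_present))
  invisible(x)
}

#' Read a signature file
#'
#' Plain text, one gene per line. Lines `#name=<label>` and
#' `#min_present=<k>` set metadata; other `#` lines are comments.
#'
#' @param path File path.
#' @return A [gene_signature()].
#' @export
read_signature <- function(path) {
  lines <- trimws(readLines(path))
  name <- sub("^#name=", "", grep("^#name=", lines, value = TRUE))
  mp <- sub("^#min_present=", "", grep("^#min_present=", lines, value = TRUE))
  genes <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(genes) == 0L)
    stop("signature file lists no genes: ", path, call. = FALSE)
  gene_signature(genes,
                 name = if (length(name)) name[1L] else
                   tools::file_path_sans_ext(basename(path)),
                 min_present = if (length(mp)) as.integer(mp[1L]) else
                   length(genes))
}

#' Write a signature file
#'
#' @param signature A [gene_signature()].
#' @param path Output path.
#' @export
write_signature <- function(signature, path) {
  writeLines(c(paste0("#name=", signature$name),
               paste0("#min_present=", signature$min_present),
               signature$genes), path)
  invisible(path)
}

#' Check signature eligibility against a matrix
#'
#' A dataset is eligible for a signature when at least `min_present` of the
#' signature genes appear among its rows. Genes absent from the matrix are
#' dropped from downstream ranking rather than imputed.
#'
#' @param matrix An [expr_matrix()].
#' @param signature A [gene_signature()].
#' @return List with `present` and `missing` gene vectors and logical
#'   `eligible`.
#' @export
signature_presence <- function(matrix, signature) {
  present <- intersect(signature$genes, rownames(matrix))
  missing <- setdiff(signature$genes, rownames(matrix))
  list(present = present, missing = missing,
       eligible = length(present) >= signature$min_present)
}

require_eligible <- function(matrix, signature) {
  pres <- signature_presence(matrix, signature)
  if (!pres$eligible)
    stop("signature '", signature$name, "' needs at least ",
         signature$min_present, " of its ", length(signature$genes),
         " genes; only ", length(pres$present), " found. Missing: ",
         paste(pres$missing, collapse = ", "), call. = FALSE)
  pres
}

#' The 19 WNT ligand gene symbols
#'
#' Human gene symbols of the 19 WNT ligands used as the default signature
#' (the paralogous mouse symbols differ only in case).
#'
#' @return Character vector of length 19.
#' @export
wnt_ligand_genes <- function() {
  c("WNT1", "WNT2", "WNT2B", "WNT3", "WNT3A", "WNT4", "WNT5A", "WNT5B",
    "WNT6", "WNT7A", "WNT7B", "WNT8A", "WNT8B", "WNT9A", "WNT9B",
    "WNT10A", "WNT10B", "WNT11", "WNT16")
}

#' The default Wnt-ligand signature
#'
#' Nineteen WNT ligand genes with the 15-of-19 eligibility floor.
#'
#' @return A [gene_signature()].
#' @export
wnt_signature <- function() {
  gene_signature(wnt_ligand_genes(), name = "WNT_ligands", min_present = 15L)
}
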