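#' Gene-by-cell UMI count matrix
#'
#' Light container for a sparse gene x cell matrix of UMI counts together
#' with the set of mitochondrial genes used by quality control.
#'
#' @param counts Matrix-like (genes in rows, cells in columns) of
#'   non-negative integer UMI counts with unique row and column names;
#'   coerced to a sparse `dgCMatrix`.
#' @param mito_genes Explicit character vector of mitochondrial gene names,
#'   or `NULL` to resolve them with `mito_pattern`.
#' @param mito_pattern Regular expression applied to gene names when
#'   `mito_genes` is `NULL` (default matches the usual `MT-`/`mt-` prefixes).
#' @return An object of class `umi_counts` with elements `counts` and
#'   `mito_genes`.
#' @export
umi_counts <- function(counts, mito_genes = NULL, mito_pattern = "^[Mm][Tt]-") {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene row names and cell column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop("gene and cell identifiers must be unique", call. = FALSE)
  }
  if (any(counts@x < 0) || any(counts@x != round(counts@x))) {
    stop("UMI counts must be non-negative integers", call. = FALSE)
  }
  if (is.null(mito_genes)) {
    mito_genes <- grep(mito_pattern, rownames(counts), value = TRUE)
  } else {
    missing <- setdiff(mito_genes, rownames(counts))
    if (length(missing) > 0) {
      stop("mito genes absent from the matrix: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(counts = counts, mito_genes = mito_genes),
            class = "umi_counts")
}

#' @export
print.umi_counts <- function(x, ...) {
  cat(sprintf("umi_counts: %d genes x %d cells (%d mitochondrial genes)\n",
              nrow(x$counts), ncol(x$counts), length(x$mito_genes)))
  invisible(x)
}

#' @export
dim.umi_counts <- function(x) dim(x$counts)

#' Read a 10x-convention Matrix Market triplet
#'
#' Loads `matrix.mtx`, `features.tsv` (first column = gene id), and
#' `barcodes.tsv` from a directory, or takes three explicit file paths.
#'
#' @param dir Directory holding `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`.
#' @param matrix_file,features_file,barcodes_file Explicit paths overriding
#'   `dir`.
#' @param ... Passed to [umi_counts()] (e.g. `mito_pattern`).
#' @return A [umi_counts()] object.
#' @export
read_10x_counts <- function(dir = NULL, matrix_file = NULL,
                            features_file = NULL, barcodes_file = NULL,
                            ...) {
  if (!is.null(dir)) {
    matrix_file <- file.path(dir, "matrix.mtx")
    features_file <- file.path(dir, "features.tsv")
    barcodes_file <- file.path(dir, "barcodes.tsv")
  }
  m <- Matrix::readMM(matrix_file)
  feats <- utils::read.table(features_file, sep = "\t",
                             stringsAsFactors = FALSE)
  bcs <- utils::read.table(barcodes_file, sep = "\t",
                           stringsAsFactors = FALSE)
  rownames(m) <- feats[[1]]
  colnames(m) <- bcs[[1]]
  umi_counts(m, ...)
}

#' Write counts as a 10x-convention Matrix Market triplet
#'
#' @param x A [umi_counts()] object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_10x_counts <- function(x, dir) {
  stopifnot(inherits(x, "umi_counts"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(rownames(x$counts)),
                     file.path(dir, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(data.frame(colnames(x$counts)),
                     file.path(dir, "barcodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(dir)
}
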