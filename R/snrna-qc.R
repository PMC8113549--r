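#' Per-cell mitochondrial UMI percentage
#'
#' `100 * (mitochondrial UMI) / (total UMI)` per cell; the standard proxy for
#' dead or degraded nuclei.
#'
#' @param x A [umi_counts()] object.
#' @param cells Optional subset of cell barcodes.
#' @return Named numeric vector of percentages.
#' @export
mito_fraction <- function(x, cells = NULL) {
  stopifnot(inherits(x, "umi_counts"))
  m <- x$counts
  if (!is.null(cells)) m <- m[, cells, drop = FALSE]
  totals <- Matrix::colSums(m)
  if (any(totals == 0)) {
    stop("zero-total cell(s): ",
         paste(utils::head(colnames(m)[totals == 0]), collapse = ", "),
         call. = FALSE)
  }
  mito <- Matrix::colSums(m[rownames(m) %in% x$mito_genes, , drop = FALSE])
  100 * mito / totals
}

#' Quality-control filter on UMI total and mitochondrial percentage
#'
#' Removes cells with more than `umi_max` total UMIs (potential doublets)
#' or more than `mito_pct_max` percent mitochondrial UMIs (dead or degraded
#' nuclei). Both comparisons are strict, so boundary cells are retained.
#' The filter is idempotent.
#'
#' @param x A [umi_counts()] object.
#' @param umi_max UMI ceiling (default 10,000).
#' @param mito_pct_max Mitochondrial percentage ceiling (default 5).
#' @return List with `counts` (filtered [umi_counts()]) and `removed`
#'   (tibble of barcode, total_umi, mito_pct, reason).
#' @export
qc_filter <- function(x, umi_max = 10000, mito_pct_max = 5) {
  stopifnot(inherits(x, "umi_counts"), umi_max > 0, mito_pct_max > 0)
  totals <- Matrix::colSums(x$counts)
  if (any(totals == 0)) {
    stop("zero-total cell(s) present; remove empty barcodes first",
         call. = FALSE)
  }
  mito_pct <- mito_fraction(x)
  too_many_umi <- totals > umi_max
  too_much_mito <- mito_pct > mito_pct_max
  drop <- too_many_umi | too_much_mito
  if (all(drop)) stop("QC removed every cell", call. = FALSE)
  reason <- ifelse(too_many_umi & too_much_mito, "umi+mito",
                   ifelse(too_many_umi, "umi", "mito"))
  removed <- tibble::tibble(
    barcode = colnames(x$counts)[drop],
    total_umi = unname(totals[drop]),
    mito_pct = unname(mito_pct[drop]),
    reason = unname(reason[drop])
  )
  filtered <- umi_counts(x$counts[, !drop, drop = FALSE],
                         mito_genes = x$mito_genes)
  list(counts = filtered, removed = removed)
}

#' Log-normalize UMI counts
#'
#' Per cell: counts are divided by the cell's total, multiplied by
#' `scale_factor`, and transformed with the natural `log(1 + x)`. Zero
#' counts stay exactly zero.
#'
#' @param x A [umi_counts()] object (QC-filtered).
#' @param scale_factor Library-size scale (default 10,000).
#' @return A sparse `dgCMatrix` of normalized values with a `scale_factor`
#'   attribute.
#' @examples
#' # a count of 10 in a 1,000-UMI cell maps to log(1 + 10/1000*1e4) = log(101)
#' @export
log_normalize <- function(x, scale_factor = 10000) {
  stopifnot(inherits(x, "umi_counts"))
  totals <- Matrix::colSums(x$counts)
  if (any(totals == 0)) {
    stop("zero-total cell(s): normalization undefined", call. = FALSE)
  }
  nm <- x$counts %*% Matrix::Diagonal(x = scale_factor / totals)
  nm <- methods::as(nm, "CsparseMatrix")
  nm@x <- log1p(nm@x)
  dimnames(nm) <- dimnames(x$counts)
  attr(nm, "scale_factor") <- scale_factor
  nm
}
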