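#' Graph-based clustering of normalized expression
#'
#' Standard single-cell clustering chain: variable-gene selection (by
#' variance of the normalized values), optional per-gene linear regression on
#' cell-level covariates (UMI total, mitochondrial percentage) with residuals
#' retained, per-gene z-scaling (clipped at 10), PCA (truncated, via
#' \pkg{irlba}), shared-nearest-neighbor graph construction
#' (\pkg{scran}), and Louvain community detection (\pkg{igraph}). Clusters
#' are renumbered 1..K by decreasing size. Deterministic for a fixed seed.
#'
#' @param nm Normalized gene x cell matrix from [log_normalize()].
#' @param n_variable_genes Number of variable genes kept (default 2,000;
#'   capped at the gene count).
#' @param n_pcs Number of principal components; `NULL` picks the elbow of
#'   the variance curve automatically (largest distance to the chord joining
#'   its endpoints).
#' @param max_pcs Components computed before elbow selection (default 30).
#' @param resolution Louvain resolution (default 0.8).
#' @param covariates Optional data frame of per-cell covariates to regress
#'   out (rows aligned with the cells); e.g. UMI totals and mito percent.
#' @param k_nn Neighbors for the SNN graph (default 20).
#' @param seed Integer seed.
#' @return An object of class `cluster_assignment`: tibble `cells`
#'   (cell, cluster), `sizes`, `pca` (cells x PCs), `n_pcs`,
#'   `variable_genes`.
#' @export
cluster_cells <- function(nm, n_variable_genes = 2000, n_pcs = NULL,
                          max_pcs = 30, resolution = 0.8, covariates = NULL,
                          k_nn = 20, seed = 1) {
  if (ncol(nm) < 2) stop("need at least 2 cells", call. = FALSE)
  gene_means <- Matrix::rowMeans(nm)
  gene_vars <- Matrix::rowMeans(nm^2) - gene_means^2
  if (all(gene_vars <= 1e-12)) {
    if (all(nm == 0)) {
      stop("degenerate matrix: rank 0", call. = FALSE)
    }
    # identical cells: nothing to separate
    return(structure(
      list(cells = tibble::tibble(cell = colnames(nm),
                                  cluster = rep(1L, ncol(nm))),
           sizes = ncol(nm), pca = NULL, n_pcs = 0L,
           variable_genes = character()),
      class = "cluster_assignment"
    ))
  }
  n_var <- min(n_variable_genes, sum(gene_vars > 0))
  vg <- names(sort(gene_vars, decreasing = TRUE))[seq_len(n_var)]
  y <- t(as.matrix(nm[vg, , drop = FALSE]))  # cells x genes, dense

  if (!is.null(covariates)) {
    X <- stats::model.matrix(~ ., data = as.data.frame(covariates))
    beta <- solve(crossprod(X), crossprod(X, y))
    y <- y - X %*% beta
  }
  mu <- colMeans(y)
  sg <- apply(y, 2, stats::sd)
  sg[sg == 0] <- 1
  y <- sweep(sweep(y, 2, mu), 2, sg, "/")
  y[y > 10] <- 10
  y[y < -10] <- -10

  max_pcs <- min(max_pcs, ncol(y) - 1, nrow(y) - 1)
  pca <- with_preserved_seed(seed, {
    irlba::prcomp_irlba(y, n = max_pcs, center = FALSE, scale. = FALSE)
  })
  if (is.null(n_pcs)) n_pcs <- elbow_point(pca$sdev^2)
  n_pcs <- min(max(n_pcs, 2), max_pcs)
  pcs <- pca$x[, seq_len(n_pcs), drop = FALSE]
  rownames(pcs) <- colnames(nm)

  graph <- scran::buildSNNGraph(pcs, transposed = TRUE,
                                k = min(k_nn, nrow(pcs) - 1L),
                                type = "jaccard")
  comm <- with_preserved_seed(seed, {
    igraph::cluster_louvain(graph, resolution = resolution)
  })
  memb <- igraph::membership(comm)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  cluster <- as.integer(relabel[as.character(memb)])
  structure(
    list(cells = tibble::tibble(cell = colnames(nm), cluster = cluster),
         sizes = as.integer(sizes),
         pca = pcs,
         n_pcs = n_pcs,
         variable_genes = vg),
    class = "cluster_assignment"
  )
}

# elbow of a decreasing variance curve: point with the largest distance to
# the chord joining the first and last points
elbow_point <- function(vars) {
  n <- length(vars)
  if (n <= 2) return(n)
  xs <- seq_len(n)
  x1 <- 1; y1 <- vars[1]; x2 <- n; y2 <- vars[n]
  num <- abs((y2 - y1) * xs - (x2 - x1) * vars + x2 * y1 - y2 * x1)
  den <- sqrt((y2 - y1)^2 + (x2 - x1)^2)
  which.max(num / den)
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d cells in %d clusters (sizes %s), %d PCs\n",
              nrow(x$cells), length(x$sizes),
              paste(x$sizes, collapse = " "), x$n_pcs))
  invisible(x)
}

#' Per-cluster expression summary of selected genes
#'
#' For each (cluster, gene): the percent of the cluster's cells expressing
#' the gene (normalized value > 0) and the mean normalized expression over
#' all the cluster's cells, zeros included.
#'
#' @param nm Normalized matrix from [log_normalize()].
#' @param clusters A [cluster_cells()] result, or a vector of cluster ids
#'   aligned with the columns of `nm`.
#' @param genes Character vector of gene names (must be present).
#' @return Tibble with columns `cluster`, `gene`, `pct_expressing`,
#'   `mean_expr`.
#' @export
marker_summary <- function(nm, clusters, genes) {
  cl <- cluster_vector(clusters, colnames(nm))
  missing <- setdiff(genes, rownames(nm))
  if (length(missing) > 0) {
    stop("unknown gene(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  sub <- nm[genes, , drop = FALSE]
  ids <- sort(unique(cl))
  out <- lapply(ids, function(k) {
    m <- sub[, cl == k, drop = FALSE]
    tibble::tibble(
      cluster = k,
      gene = genes,
      pct_expressing = unname(100 * Matrix::rowSums(m > 0) / ncol(m)),
      mean_expr = unname(Matrix::rowMeans(m))
    )
  })
  do.call(rbind, out)
}

# accepts a cluster_assignment or a bare vector; returns per-cell ids
# aligned with `cells`
cluster_vector <- function(clusters, cells) {
  if (inherits(clusters, "cluster_assignment")) {
    v <- stats::setNames(clusters$cells$cluster, clusters$cells$cell)
    missing <- setdiff(cells, names(v))
    if (length(missing) > 0) {
      stop("cells without cluster assignment: ",
           paste(utils::head(missing), collapse = ", "), call. = FALSE)
    }
    unname(v[cells])
  } else {
    if (length(clusters) != length(cells)) {
      stop("cluster vector length must match cell count", call. = FALSE)
    }
    as.vector(clusters)
  }
}
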