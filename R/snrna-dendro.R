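#' Bootstrapped dendrogram of cluster expression profiles
#'
#' Hierarchical clustering of per-cluster mean expression profiles over the
#' union of each cluster's top fold-change genes (fold change = mean
#' ln-normalized expression in the cluster minus the mean outside it), with
#' correlation distance (1 - Pearson r) and average-linkage agglomeration.
#' Node support is the fraction of gene-resampled bootstrap replicates in
#' which the same leaf set reappears as a clade.
#'
#' @param nm Normalized matrix from [log_normalize()].
#' @param clusters A [cluster_cells()] result or cluster id vector.
#' @param top_n_genes Top fold-change genes kept per cluster (default 50).
#' @param n_boot Bootstrap replicates over genes (default 100).
#' @param seed Integer seed.
#' @return An object of class `cluster_dendrogram` with fields `hclust`,
#'   `support` (per internal node, in [0, 1]), `genes`, `profiles`.
#' @export
bootstrap_dendrogram <- function(nm, clusters, top_n_genes = 50,
                                 n_boot = 100, seed = 1) {
  cl <- cluster_vector(clusters, colnames(nm))
  ids <- sort(unique(cl))
  if (length(ids) < 2) stop("need at least 2 clusters", call. = FALSE)
  means <- vapply(ids, function(k) {
    Matrix::rowMeans(nm[, cl == k, drop = FALSE])
  }, numeric(nrow(nm)))
  colnames(means) <- as.character(ids)
  grand <- Matrix::rowMeans(nm)
  n_cells <- vapply(ids, function(k) sum(cl == k), numeric(1))
  top <- unlist(lapply(seq_along(ids), function(j) {
    # mean outside the cluster, from the grand mean
    out_mean <- (grand * length(cl) - means[, j] * n_cells[j]) /
      (length(cl) - n_cells[j])
    fc <- means[, j] - out_mean
    rownames(means)[order(fc, decreasing = TRUE)[seq_len(
      min(top_n_genes, nrow(means)))]]
  }))
  genes <- unique(top)
  profiles <- means[genes, , drop = FALSE]

  hc_of <- function(m) {
    cors <- suppressWarnings(stats::cor(m))
    cors[!is.finite(cors)] <- 0
    stats::hclust(stats::as.dist(1 - cors), method = "average")
  }
  hc <- hc_of(profiles)

  clades_of <- function(h) {
    n <- length(h$labels)
    sets <- vector("list", nrow(h$merge))
    for (i in seq_len(nrow(h$merge))) {
      members <- unlist(lapply(h$merge[i, ], function(j) {
        if (j < 0) h$labels[-j] else sets[[j]]
      }))
      sets[[i]] <- sort(members)
    }
    vapply(sets, paste, character(1), collapse = "\r")
  }
  ref_clades <- clades_of(hc)
  hits <- numeric(length(ref_clades))
  with_preserved_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample(nrow(profiles), replace = TRUE)
      boot_clades <- clades_of(hc_of(profiles[idx, , drop = FALSE]))
      hits <- hits + (ref_clades %in% boot_clades)
    }
  })
  structure(
    list(hclust = hc, support = hits / n_boot, genes = genes,
         profiles = profiles),
    class = "cluster_dendrogram"
  )
}

#' @export
print.cluster_dendrogram <- function(x, ...) {
  cat(sprintf("cluster_dendrogram: %d clusters over %d genes\n",
              length(x$hclust$labels), length(x$genes)))
  cat("  node support:", paste(sprintf("%.2f", x$support), collapse = " "),
      "\n")
  invisible(x)
}

#' Write a cluster dendrogram in Newick format
#'
#' Bootstrap supports are attached as internal node labels.
#'
#' @param x A [bootstrap_dendrogram()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(x, path) {
  stopifnot(inherits(x, "cluster_dendrogram"))
  phy <- ape::as.phylo(x$hclust)
  # hclust merge rows correspond 1:1 to internal nodes; map supports onto
  # the phylo node order via clade membership
  n_tip <- length(phy$tip.label)
  clade_key <- function(tree, node) {
    paste(sort(ape::extract.clade(tree, node)$tip.label), collapse = "\r")
  }
  hc_sets <- local({
    h <- x$hclust
    sets <- vector("list", nrow(h$merge))
    for (i in seq_len(nrow(h$merge))) {
      sets[[i]] <- sort(unlist(lapply(h$merge[i, ], function(j) {
        if (j < 0) h$labels[-j] else sets[[j]]
      })))
    }
    vapply(sets, paste, character(1), collapse = "\r")
  })
  node_labels <- vapply((n_tip + 1):(n_tip + phy$Nnode), function(nd) {
    key <- clade_key(phy, nd)
    hit <- match(key, hc_sets)
    if (is.na(hit)) "" else sprintf("%.2f", x$support[hit])
  }, character(1))
  phy$node.label <- node_labels
  ape::write.tree(phy, file = path)
  invisible(path)
}
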