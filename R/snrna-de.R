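#' Differential expression between pathway groups
#'
#' Wilcoxon rank-sum differential expression between two cell groups (e.g.
#' direct-like vs indirect-like pathway MSNs), following the conventional
#' single-cell marker-test recipe: genes are pre-filtered to those expressed
#' in at least `min_pct` of either group with an absolute log fold change of
#' at least `logfc_threshold` (difference of mean ln-normalized expression);
#' each group is subsampled to at most `max_cells_per_ident` cells (seeded);
#' p-values are Bonferroni-adjusted over the genes tested. Genes with
#' adjusted or raw p below `alpha` are labeled by the enriched group.
#'
#' @param nm Normalized matrix from [log_normalize()].
#' @param cells1,cells2 Cell barcodes of the two groups (non-empty,
#'   disjoint).
#' @param labels Group labels used in the `enriched` column.
#' @param min_pct Minimum expression fraction in at least one group
#'   (default 0.1).
#' @param logfc_threshold Minimum |log fold change| (default 0.25).
#' @param max_cells_per_ident Per-group subsample ceiling (default 200).
#' @param alpha Significance level for the direction label (default 0.001,
#'   applied to the raw rank-sum p as in the figure convention).
#' @param seed Seed for the subsample.
#' @return Tibble with columns `gene`, `logfc` (group1 - group2), `pct1`,
#'   `pct2`, `p`, `p_adj`, `enriched`.
#' @export
pathway_de <- function(nm, cells1, cells2,
                       labels = c("direct-like", "indirect-like"),
                       min_pct = 0.1, logfc_threshold = 0.25,
                       max_cells_per_ident = 200, alpha = 0.001, seed = 1) {
  if (length(cells1) == 0 || length(cells2) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  subsample <- function(cells, offset) {
    if (length(cells) <= max_cells_per_ident) return(cells)
    with_preserved_seed(seed + offset,
                        sample(cells, max_cells_per_ident))
  }
  cells1 <- subsample(cells1, 0L)
  cells2 <- subsample(cells2, 1L)
  m1 <- nm[, cells1, drop = FALSE]
  m2 <- nm[, cells2, drop = FALSE]
  pct1 <- Matrix::rowSums(m1 > 0) / ncol(m1)
  pct2 <- Matrix::rowSums(m2 > 0) / ncol(m2)
  logfc <- Matrix::rowMeans(m1) - Matrix::rowMeans(m2)
  keep <- (pmax(pct1, pct2) >= min_pct) & (abs(logfc) >= logfc_threshold)
  genes <- rownames(nm)[keep]
  if (length(genes) == 0) {
    return(tibble::tibble(gene = character(), logfc = numeric(),
                          pct1 = numeric(), pct2 = numeric(), p = numeric(),
                          p_adj = numeric(), enriched = character()))
  }
  p <- vapply(genes, function(g) {
    stats::wilcox.test(as.numeric(m1[g, ]), as.numeric(m2[g, ]))$p.value
  }, numeric(1))
  p_adj <- stats::p.adjust(p, method = "bonferroni")
  lfc <- unname(logfc[keep])
  enriched <- ifelse(p < alpha, ifelse(lfc > 0, labels[1], labels[2]), "ns")
  out <- tibble::tibble(
    gene = genes,
    logfc = lfc,
    pct1 = unname(pct1[keep]),
    pct2 = unname(pct2[keep]),
    p = unname(p),
    p_adj = unname(p_adj),
    enriched = unname(enriched)
  )
  out[order(out$p_adj, -abs(out$logfc)), ]
}

#' Welch's t-test for receptor-expression shifts between conditions
#'
#' Compares the normalized expression of a receptor gene between two
#' conditions (e.g. control vs knockdown), within cells grouped by their
#' dopamine-receptor expression pattern over Drd1/Drd5/Drd2 (e.g. `D1+`
#' means Drd1 only). Uses Welch's unequal-variance t-test per group.
#'
#' @param nm1,nm2 Normalized matrices of the two conditions.
#' @param cells1,cells2 Cell barcodes to consider in each condition
#'   (typically FoxP2+ MSNs).
#' @param gene Receptor gene tested (default `"Drd1"`).
#' @param receptor_genes Genes defining the expression-pattern groups.
#' @param min_value Expression threshold for the pattern call.
#' @return Tibble with columns `group`, `n1`, `n2`, `mean1`, `mean2`,
#'   `t`, `df`, `p`, `direction` (sign of condition1 - condition2).
#' @export
receptor_shift_test <- function(nm1, nm2, cells1 = NULL, cells2 = NULL,
                                gene = "Drd1",
                                receptor_genes = c(D1 = "Drd1", D5 = "Drd5",
                                                   D2 = "Drd2"),
                                min_value = 0) {
  if (is.null(cells1)) cells1 <- colnames(nm1)
  if (is.null(cells2)) cells2 <- colnames(nm2)
  pattern_of <- function(nm, cells) {
    expr <- as.matrix(nm[unname(receptor_genes), cells, drop = FALSE]) >
      min_value
    rownames(expr) <- names(receptor_genes)
    apply(expr, 2, function(v) {
      pos <- names(v)[v]
      if (length(pos) == 0) "none" else
        paste(paste0(pos, "+"), collapse = "/")
    })
  }
  pat1 <- pattern_of(nm1, cells1)
  pat2 <- pattern_of(nm2, cells2)
  groups <- intersect(unique(pat1), unique(pat2))
  groups <- setdiff(groups, "none")
  if (length(groups) == 0) {
    stop("no receptor-expression group present in both conditions",
         call. = FALSE)
  }
  out <- lapply(sort(groups), function(g) {
    x <- as.numeric(nm1[gene, cells1[pat1 == g]])
    y <- as.numeric(nm2[gene, cells2[pat2 == g]])
    if (length(x) < 2 || length(y) < 2) {
      stop("group '", g, "' has fewer than 2 cells in a condition",
           call. = FALSE)
    }
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      tt <- list(statistic = c(t = 0), parameter = c(df = NA_real_),
                 p.value = 1)
    } else {
      tt <- stats::t.test(x, y, var.equal = FALSE)
    }
    tibble::tibble(group = g, n1 = length(x), n2 = length(y),
                   mean1 = mean(x), mean2 = mean(y),
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p = tt$p.value,
                   direction = sign(mean(x) - mean(y)))
  })
  do.call(rbind, out)
}
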