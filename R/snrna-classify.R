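#' Marker-gene table for Area X cluster identities
#'
#' The literature-established marker genes used to assign functional
#' identities to Area X clusters: Gad2 (GABAergic), Slc17a6 (glutamatergic),
#' Ppp1r1b/FoxP1/FoxP2/Tac1 (MSN), Penk/Tshz1 (pallidal-like projection
#' neuron), Pvalb/Sst/Npy/Nos1/Chat (interneurons), Lhx6/Meis2
#' (developmental origin), and glial markers. The `zf` flag marks genes
#' whose Area X expression was established in zebra finches specifically.
#'
#' @return Tibble with columns `gene`, `identity`, `zf`.
#' @export
marker_table <- function() {
  tibble::tribble(
    ~gene,      ~identity,                  ~zf,
    "Gad2",     "GABAergic",                FALSE,
    "Slc17a6",  "Glutamatergic",            FALSE,
    "Lhx6",     "MGE-derived",              FALSE,
    "Pvalb",    "Interneuron",              TRUE,
    "Sst",      "Interneuron",              TRUE,
    "Npy",      "Interneuron",              TRUE,
    "Nos1",     "Interneuron",              TRUE,
    "Chat",     "Interneuron",              TRUE,
    "Penk",     "PN",                       TRUE,
    "Tshz1",    "PN",                       TRUE,
    "Lrig1",    "Astrocyte",                FALSE,
    "Meis2",    "LGE-derived",              FALSE,
    "Ppp1r1b",  "MSN",                      TRUE,
    "FoxP1",    "MSN",                      TRUE,
    "FoxP2",    "MSN",                      TRUE,
    "Tac1",     "MSN",                      TRUE,
    "Csf1r",    "Microglia",                FALSE,
    "Flt1",     "Endothelial",              FALSE,
    "Mbp",      "Oligodendrocyte",          FALSE,
    "Pdgfra",   "Oligodendrocyte Precursor", FALSE
  )
}

# identity -> markers and how they combine ("all" = joint enrichment,
# "any" = any one marker suffices). MSN calls require the joint expression
# of Gad2, Ppp1r1b and FoxP1.
identity_rules <- function() {
  list(
    MSN = list(markers = c("Gad2", "Ppp1r1b", "FoxP1"), mode = "all"),
    PN = list(markers = c("Penk"), mode = "all"),
    Interneuron = list(markers = c("Pvalb", "Sst", "Npy", "Nos1", "Chat"),
                       mode = "any"),
    Glutamatergic = list(markers = c("Slc17a6"), mode = "all"),
    Astrocyte = list(markers = c("Lrig1"), mode = "all"),
    Oligodendrocyte = list(markers = c("Mbp"), mode = "all"),
    `Oligodendrocyte Precursor` = list(markers = c("Pdgfra"), mode = "all"),
    Microglia = list(markers = c("Csf1r"), mode = "all"),
    Endothelial = list(markers = c("Flt1"), mode = "all")
  )
}

#' Assign functional identities to clusters from marker expression
#'
#' Rule-based typing on per-cluster marker summaries: an identity's score is
#' the minimum (joint markers, e.g. MSN = Gad2 + Ppp1r1b + FoxP1) or maximum
#' (interchangeable markers, e.g. the interneuron set) percent of cells
#' expressing its markers; the best-scoring identity at or above
#' `min_pct` wins, and clusters with no identity above threshold are labeled
#' `"unassigned"`.
#'
#' @param nm Normalized matrix from [log_normalize()].
#' @param clusters A [cluster_cells()] result or cluster id vector.
#' @param table Marker table (default [marker_table()]); only its genes that
#'   are present in `nm` are used.
#' @param min_pct Minimum percent of cells expressing (default 50).
#' @return Tibble with columns `cluster`, `identity`, `score`.
#' @export
assign_cell_types <- function(nm, clusters, table = marker_table(),
                              min_pct = 50) {
  if (nrow(table) == 0) stop("empty marker table", call. = FALSE)
  rules <- identity_rules()
  rules <- lapply(rules, function(r) {
    present <- intersect(intersect(r$markers, table$gene), rownames(nm))
    # joint-enrichment identities need every marker measurable
    if (r$mode == "all" && length(present) < length(r$markers)) return(NULL)
    r$markers <- present
    r
  })
  rules <- Filter(function(r) !is.null(r) && length(r$markers) > 0, rules)
  if (length(rules) == 0) {
    stop("no marker genes present in the matrix", call. = FALSE)
  }
  genes <- unique(unlist(lapply(rules, `[[`, "markers")))
  summ <- marker_summary(nm, clusters, genes)
  ids <- sort(unique(summ$cluster))
  out <- lapply(ids, function(k) {
    pct <- stats::setNames(summ$pct_expressing[summ$cluster == k],
                           summ$gene[summ$cluster == k])
    scores <- vapply(rules, function(r) {
      if (r$mode == "all") min(pct[r$markers]) else max(pct[r$markers])
    }, numeric(1))
    best <- which.max(scores)
    tibble::tibble(
      cluster = k,
      identity = if (scores[best] >= min_pct) names(rules)[best] else
        "unassigned",
      score = unname(scores[best])
    )
  })
  do.call(rbind, out)
}

#' Exclusive dopamine-receptor classification of cells
#'
#' Partitions cells by the exclusive expression of the D1-family receptors
#' Drd1/Drd5 versus Drd2 (expression = normalized value > 0, i.e. at least
#' one UMI; raise `min_value` for a stricter call), and flags FoxP2
#' co-expression:
#' \itemize{
#'   \item `D1/5-only`: (Drd1 or Drd5) expressed, Drd2 silent
#'   \item `D2-only`: Drd2 expressed, Drd1 and Drd5 silent
#'   \item `both`: (Drd1 or Drd5) and Drd2 expressed
#'   \item `none`: no dopamine receptor expressed
#' }
#'
#' @param nm Normalized matrix from [log_normalize()].
#' @param cells Optional subset of cell barcodes (e.g. MSN-cluster cells).
#' @param genes Named vector giving the receptor/FoxP2 gene names in `nm`.
#' @param min_value Expression threshold (default 0: any positive value).
#' @return Tibble with columns `cell`, `class` (factor with the four levels
#'   above), `foxp2` (logical).
#' @export
receptor_class <- function(nm, cells = NULL,
                           genes = c(drd1 = "Drd1", drd5 = "Drd5",
                                     drd2 = "Drd2", foxp2 = "FoxP2"),
                           min_value = 0) {
  missing <- setdiff(unname(genes), rownames(nm))
  if (length(missing) > 0) {
    stop("receptor gene(s) absent from the matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(cells)) cells <- colnames(nm)
  expr <- as.matrix(nm[unname(genes), cells, drop = FALSE]) > min_value
  rownames(expr) <- names(genes)
  d15 <- expr["drd1", ] | expr["drd5", ]
  d2 <- expr["drd2", ]
  cls <- ifelse(d15 & !d2, "D1/5-only",
                ifelse(!d15 & d2, "D2-only",
                       ifelse(d15 & d2, "both", "none")))
  tibble::tibble(
    cell = cells,
    class = factor(cls, levels = c("D1/5-only", "D2-only", "both", "none")),
    foxp2 = unname(expr["foxp2", ])
  )
}

#' Receptor-class composition and FoxP2 co-expression of MSNs
#'
#' Summarizes a [receptor_class()] table (typically restricted to
#' MSN-cluster cells): the percentage of cells in each exclusive receptor
#' class (summing to 100) and, within each class, the percentage expressing
#' FoxP2.
#'
#' @param rc Tibble from [receptor_class()].
#' @return Tibble with columns `class`, `n`, `pct_of_cells`,
#'   `pct_foxp2_within`.
#' @export
coexpression_summary <- function(rc) {
  if (nrow(rc) == 0) stop("no cells to summarize", call. = FALSE)
  total <- nrow(rc)
  out <- lapply(levels(rc$class), function(cl) {
    sub <- rc[rc$class == cl, ]
    tibble::tibble(
      class = cl,
      n = nrow(sub),
      pct_of_cells = 100 * nrow(sub) / total,
      pct_foxp2_within = if (nrow(sub) > 0) 100 * mean(sub$foxp2) else
        NA_real_
    )
  })
  do.call(rbind, out)
}

#' Direct-like / indirect-like pathway grouping
#'
#' Groups MSN clusters into a putative direct-like pathway (Drd1+/FoxP2+
#' enriched clusters; default clusters 1 and 5) and indirect-like pathway
#' (clusters containing the Drd2+ cells; default clusters 2, 3 and 4).
#'
#' @param direct_like,indirect_like Disjoint integer sets of cluster ids.
#' @return An object of class `pathway_grouping`.
#' @export
pathway_grouping <- function(direct_like = c(1L, 5L),
                             indirect_like = c(2L, 3L, 4L)) {
  if (length(intersect(direct_like, indirect_like)) > 0) {
    stop("pathway groups must be disjoint", call. = FALSE)
  }
  structure(list(direct_like = as.integer(direct_like),
                 indirect_like = as.integer(indirect_like)),
            class = "pathway_grouping")
}
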