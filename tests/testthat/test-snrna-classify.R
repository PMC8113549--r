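# build a normalized matrix with prescribed marker expression per cluster:
# `clusters` assigns cells, `hot` maps cluster -> character vector of genes
# expressed in (almost) every cell of the cluster
marker_toy <- function(clusters, hot, n_genes_extra = 3) {
  genes <- unique(c(unlist(hot), sprintf("f%02d", seq_len(n_genes_extra))))
  n <- length(clusters)
  m <- matrix(0, length(genes), n, dimnames = list(genes, sprintf("c%03d", 1:n)))
  for (k in names(hot)) {
    cells <- which(clusters == as.integer(k))
    m[hot[[k]], cells] <- 5
  }
  m[sprintf("f%02d", seq_len(n_genes_extra)), ] <- 1
  x <- umi_counts(m)
  log_normalize(x)
}

test_that("joint MSN markers and single glial markers drive typing", {
  clusters <- rep(c(1, 2, 3), each = 10)
  nm <- marker_toy(clusters, list(
    `1` = c("Gad2", "Ppp1r1b", "FoxP1", "Tac1"),
    `2` = c("Mbp"),
    `3` = c("f01")  # nothing marker-like
  ))
  ty <- assign_cell_types(nm, clusters)
  expect_equal(ty$identity[ty$cluster == 1], "MSN")
  expect_equal(ty$identity[ty$cluster == 2], "Oligodendrocyte")
  expect_equal(ty$identity[ty$cluster == 3], "unassigned")
})

test_that("partial MSN marker expression does not produce an MSN call", {
  clusters <- rep(c(1, 2), each = 8)
  nm <- marker_toy(clusters, list(
    `1` = c("Gad2", "Pvalb"),       # GABAergic interneuron-like
    `2` = c("Gad2", "Penk", "Tshz1")  # pallidal-like
  ))
  ty <- assign_cell_types(nm, clusters)
  expect_equal(ty$identity[ty$cluster == 1], "Interneuron")
  expect_equal(ty$identity[ty$cluster == 2], "PN")
  expect_error(assign_cell_types(nm, clusters,
                                 table = marker_table()[0, ]), "empty")
})

test_that("simulated Area X programs type correctly end to end", {
  spec <- area_x_preset(n_cells = 1500, doublet_rate = 0)
  sim <- simulate_counts(spec, seed = 4)
  qc <- qc_filter(sim$counts)
  nm <- log_normalize(qc$counts)
  cl <- cluster_cells(nm, seed = 1)
  ty <- assign_cell_types(nm, cl)
  truth <- sim$truth[match(colnames(nm), sim$truth$barcode), ]
  # every cluster dominated by MSN cells must be typed MSN, and so on
  for (k in ty$cluster) {
    members <- truth$program[cl$cells$cluster == k]
    dominant <- names(sort(table(members), decreasing = TRUE))[1]
    expected <- switch(dominant,
                       "MSN-direct-like" = "MSN",
                       "MSN-indirect-like" = "MSN",
                       "PN" = "PN",
                       "Interneuron" = "Interneuron",
                       "Astrocyte" = "Astrocyte",
                       "Oligodendrocyte" = "Oligodendrocyte")
    expect_equal(ty$identity[ty$cluster == k], expected)
  }
})

test_that("receptor classes partition cells by exclusive expression", {
  genes <- c("Drd1", "Drd5", "Drd2", "FoxP2", "f01")
  m <- matrix(0, 5, 4, dimnames = list(genes, sprintf("c%d", 1:4)))
  m["Drd1", 1] <- 2                      # D1/5-only
  m["Drd1", 2] <- 1; m["Drd2", 2] <- 1   # both
  m["Drd2", 3] <- 3; m["FoxP2", 3] <- 1  # D2-only, FoxP2+
  m["f01", ] <- 1                        # keep totals positive
  nm <- log_normalize(umi_counts(m))
  rc <- receptor_class(nm)
  expect_equal(as.character(rc$class),
               c("D1/5-only", "both", "D2-only", "none"))
  expect_equal(rc$foxp2, c(FALSE, FALSE, TRUE, FALSE))
  expect_error(receptor_class(nm[-1, , drop = FALSE]), "absent")
})

test_that("co-expression summaries sum to 100 and track FoxP2 rates", {
  rc <- tibble::tibble(
    cell = sprintf("c%d", 1:10),
    class = factor(c(rep("D1/5-only", 6), rep("D2-only", 4)),
                   levels = c("D1/5-only", "D2-only", "both", "none")),
    foxp2 = c(rep(TRUE, 6), rep(c(TRUE, FALSE), 2))
  )
  cs <- coexpression_summary(rc)
  expect_equal(sum(cs$pct_of_cells), 100)
  expect_equal(cs$pct_of_cells[cs$class == "D1/5-only"], 60)
  expect_equal(cs$pct_foxp2_within[cs$class == "D1/5-only"], 100)
  expect_equal(cs$pct_foxp2_within[cs$class == "D2-only"], 50)
  expect_error(coexpression_summary(rc[0, ]), "no cells")

  set.seed(14)
  rnd <- tibble::tibble(
    cell = sprintf("c%d", 1:50),
    class = factor(sample(c("D1/5-only", "D2-only", "both", "none"), 50,
                          replace = TRUE),
                   levels = c("D1/5-only", "D2-only", "both", "none")),
    foxp2 = sample(c(TRUE, FALSE), 50, replace = TRUE)
  )
  expect_equal(sum(coexpression_summary(rnd)$pct_of_cells), 100)
})

test_that("pathway groupings stay disjoint with the Area X defaults", {
  pg <- pathway_grouping()
  expect_equal(pg$direct_like, c(1L, 5L))
  expect_equal(pg$indirect_like, c(2L, 3L, 4L))
  expect_error(pathway_grouping(c(1, 2), c(2, 3)), "disjoint")
})
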