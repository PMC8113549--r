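# dense toy count matrix -> umi_counts; rows named g1..gG plus optional
# mito rows named mt-1..
toy_counts <- function(m, mito_rows = integer()) {
  genes <- sprintf("g%02d", seq_len(nrow(m)))
  if (length(mito_rows) > 0) {
    genes[mito_rows] <- sprintf("mt-%d", seq_along(mito_rows))
  }
  rownames(m) <- genes
  colnames(m) <- sprintf("c%02d", seq_len(ncol(m)))
  umi_counts(m)
}

# small multi-program simulation spec with distinct signature blocks and no
# receptor program (for clustering-recovery tests)
separated_programs_spec <- function(props, n_cells, doublet_rate = 0) {
  filler <- stats::setNames(rep(c(2, 5, 8, 12, 20), length.out = 100),
                            sprintf("G%03d", 1:100))
  sig <- function(p) stats::setNames(rep(6, 15),
                                     paste0(p, sprintf("%02d", 1:15)))
  prefixes <- c("AAA", "BBB", "CCC", "DDD")[seq_along(props)]
  progs <- lapply(seq_along(props), function(i) {
    cell_program(LETTERS[i], props[i], c(filler, sig(prefixes[i])))
  })
  simulation_spec(progs, n_cells = n_cells, doublet_rate = doublet_rate)
}
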