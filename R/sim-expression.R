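#' Cell program for the expression simulator
#'
#' A generative description of one cell population: its share of the cell
#' mixture, a negative-binomial expression profile, an optional exclusive
#' dopamine-receptor/FoxP2 co-occurrence program (MSN-like populations), a
#' mitochondrial-fraction law, and a library-size law.
#'
#' @param label Program name (e.g. `"MSN-direct-like"`).
#' @param proportion Share of cells in the mixture (programs must sum to 1).
#' @param gene_means Named non-negative vector of relative expected counts;
#'   genes absent from a program's vector are treated as 0. Counts are
#'   NB-sampled around these means rescaled to the drawn library size.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2;
#'   default 0.3, typical for UMI data).
#' @param receptor_probs Probabilities of the four exclusive receptor
#'   classes, in the order D1/5-only, D2-only, both, none; `NULL` for
#'   populations without a receptor program.
#' @param foxp2_given_class FoxP2-positive probability within each receptor
#'   class (same order); ignored when `receptor_probs` is `NULL`.
#' @param mito_beta Shape parameters of the Beta law for the per-cell
#'   mitochondrial UMI fraction (default Beta(2, 78): mean 2.5%).
#' @param lib_median,lib_sdlog Median and log-SD of the lognormal library
#'   size law.
#' @return An object of class `cell_program`.
#' @export
cell_program <- function(label, proportion, gene_means, dispersion = 0.3,
                         receptor_probs = NULL,
                         foxp2_given_class = c(0.61, 0.21, 0.50, 0.40),
                         mito_beta = c(2, 78),
                         lib_median = 6500, lib_sdlog = 0.15) {
  stopifnot(proportion > 0, proportion <= 1, dispersion > 0,
            all(gene_means >= 0), !is.null(names(gene_means)))
  if (!is.null(receptor_probs)) {
    stopifnot(length(receptor_probs) == 4,
              abs(sum(receptor_probs) - 1) < 1e-9,
              all(receptor_probs >= 0),
              all(foxp2_given_class >= 0 & foxp2_given_class <= 1))
  }
  structure(
    list(label = label, proportion = proportion, gene_means = gene_means,
         dispersion = dispersion, receptor_probs = receptor_probs,
         foxp2_given_class = foxp2_given_class, mito_beta = mito_beta,
         lib_median = lib_median, lib_sdlog = lib_sdlog),
    class = "cell_program"
  )
}

#' Simulation specification for a synthetic UMI matrix
#'
#' @param programs List of [cell_program()]s; proportions must sum to 1.
#' @param n_cells Total cells, doublets included.
#' @param doublet_rate Fraction of cells that are doublets (two random
#'   singlets' counts summed), in `[0, 1)`.
#' @param mito_genes Names of the mitochondrial gene set.
#' @param receptor_genes Names of the receptor/FoxP2 genes used by the
#'   co-occurrence program.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(programs, n_cells, doublet_rate = 0,
                            mito_genes = paste0("mt-", c(
                              "Nd1", "Nd2", "Co1", "Co2", "Atp8", "Atp6",
                              "Co3", "Nd3", "Nd4l", "Nd4", "Nd5", "Nd6",
                              "Cytb")),
                            receptor_genes = c(drd1 = "Drd1", drd5 = "Drd5",
                                               drd2 = "Drd2",
                                               foxp2 = "FoxP2")) {
  stopifnot(n_cells >= 1, doublet_rate >= 0, doublet_rate < 1,
            length(programs) >= 1)
  props <- vapply(programs, `[[`, numeric(1), "proportion")
  if (abs(sum(props) - 1) > 1e-6) {
    stop("program proportions must sum to 1 (got ", sum(props), ")",
         call. = FALSE)
  }
  genes <- unique(c(unlist(lapply(programs, function(p) names(p$gene_means))),
                    unname(receptor_genes), mito_genes))
  structure(
    list(programs = programs, n_cells = as.integer(n_cells),
         doublet_rate = doublet_rate, genes = genes,
         mito_genes = mito_genes, receptor_genes = receptor_genes),
    class = "simulation_spec"
  )
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf("simulation_spec: %d cells, %d genes, doublet rate %.3f\n",
              x$n_cells, length(x$genes), x$doublet_rate))
  for (p in x$programs) {
    cat(sprintf("  %s: %.1f%%%s\n", p$label, 100 * p$proportion,
                if (is.null(p$receptor_probs)) "" else
                  paste0(" (receptor classes ",
                         paste(round(100 * p$receptor_probs), collapse = "/"),
                         ")")))
  }
  invisible(x)
}

#' Simulate a gene-by-cell UMI matrix with ground truth
#'
#' Draws cells from the programs of a [simulation_spec()]: per cell a
#' library size and mitochondrial fraction are drawn, non-mitochondrial
#' counts are NB-sampled around the program profile rescaled to the library,
#' the mitochondrial share is allocated binomially over the mito gene set,
#' and receptor/FoxP2 genes are gated on the cell's sampled co-occurrence
#' status (a positive status guarantees at least one UMI, a negative status
#' exactly zero, so the programmed co-occurrence is exact). Doublets are
#' formed by summing the counts of two random singlets. Deterministic per
#' seed.
#'
#' @param spec A [simulation_spec()].
#' @param seed Integer seed.
#' @return List with `counts` (a [umi_counts()]) and `truth` (tibble:
#'   barcode, program, receptor_class, foxp2, doublet).
#' @export
simulate_counts <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_preserved_seed(seed, {
    n_doub <- round(spec$doublet_rate * spec$n_cells)
    n_sing <- spec$n_cells - n_doub
    props <- vapply(spec$programs, `[[`, numeric(1), "proportion")
    prog_idx <- sample(length(spec$programs), n_sing, replace = TRUE,
                       prob = props)
    genes <- spec$genes
    G <- length(genes)
    rg <- spec$receptor_genes
    special <- c(unname(rg), spec$mito_genes)
    counts <- matrix(0L, nrow = G, ncol = n_sing,
                     dimnames = list(genes, NULL))
    truth_class <- rep(NA_character_, n_sing)
    truth_foxp2 <- rep(NA, n_sing)
    class_levels <- c("D1/5-only", "D2-only", "both", "none")

    for (pi in seq_along(spec$programs)) {
      prog <- spec$programs[[pi]]
      cols <- which(prog_idx == pi)
      if (length(cols) == 0) next
      nc <- length(cols)
      L <- round(prog$lib_median * exp(stats::rnorm(nc, 0, prog$lib_sdlog)))
      f <- stats::rbeta(nc, prog$mito_beta[1], prog$mito_beta[2])

      prof <- stats::setNames(numeric(G), genes)
      prof[names(prog$gene_means)] <- prog$gene_means
      prof[special] <- 0
      share <- prof / sum(prof)
      body_genes <- which(share > 0)
      mu <- outer(share[body_genes], L * (1 - f))
      draws <- matrix(
        stats::rnbinom(length(mu), mu = mu, size = 1 / prog$dispersion),
        nrow = length(body_genes))
      counts[body_genes, cols] <- draws

      # mitochondrial share
      m_tot <- stats::rbinom(nc, L, f)
      n_mito <- length(spec$mito_genes)
      mito_draws <- vapply(m_tot, function(m) {
        as.integer(stats::rmultinom(1, m, rep(1, n_mito)))
      }, integer(n_mito))
      counts[spec$mito_genes, cols] <- mito_draws

      # receptor / FoxP2 status
      if (!is.null(prog$receptor_probs)) {
        cls <- sample(4, nc, replace = TRUE, prob = prog$receptor_probs)
        fox <- stats::runif(nc) < prog$foxp2_given_class[cls]
        d15 <- cls %in% c(1, 3)
        d2 <- cls %in% c(2, 3)
        drd1 <- d15 & (stats::runif(nc) < 0.85)
        drd5 <- d15 & (stats::runif(nc) < 0.30)
        none15 <- d15 & !drd1 & !drd5
        drd1[none15] <- TRUE
        gate <- function(on) {
          out <- integer(nc)
          out[on] <- 1L + stats::rpois(sum(on), 0.7)
          out
        }
        counts[rg[["drd1"]], cols] <- gate(drd1)
        counts[rg[["drd5"]], cols] <- gate(drd5)
        counts[rg[["drd2"]], cols] <- gate(d2)
        counts[rg[["foxp2"]], cols] <- gate(fox)
        truth_class[cols] <- class_levels[cls]
        truth_foxp2[cols] <- fox
      }
    }

    prog_labels <- vapply(spec$programs, `[[`, character(1), "label")
    truth <- tibble::tibble(
      barcode = sprintf("cell%05d", seq_len(spec$n_cells)),
      program = c(prog_labels[prog_idx], rep("doublet", n_doub)),
      receptor_class = c(truth_class, rep(NA_character_, n_doub)),
      foxp2 = c(truth_foxp2, rep(NA, n_doub)),
      doublet = c(rep(FALSE, n_sing), rep(TRUE, n_doub))
    )
    if (n_doub > 0) {
      pairs <- vapply(seq_len(n_doub), function(i) {
        sample(n_sing, 2)
      }, integer(2))
      doub <- counts[, pairs[1, ], drop = FALSE] +
        counts[, pairs[2, ], drop = FALSE]
      counts <- cbind(counts, doub)
    }
    colnames(counts) <- truth$barcode
    list(counts = umi_counts(counts, mito_genes = spec$mito_genes),
         truth = truth)
  })
}

#' Packaged Area X-like simulation specification
#'
#' A ready-made [simulation_spec()] whose programmed composition mirrors the
#' Area X census used throughout the package's recovery tests: 68% MSNs
#' (split between a direct-like and an indirect-like program), 2.4%
#' pallidal-like projection neurons, and interneuron/astrocyte/
#' oligodendrocyte programs for the remainder. Across the two MSN programs
#' the exclusive receptor classes average 36% Drd1/5-only, 13% Drd2-only,
#' 18% both and 33% neither, with FoxP2 co-expression of 61% within
#' Drd1/5-only cells and 21% within Drd2-only cells (the two rates that are
#' empirically anchored; rates for the `both`/`none` classes are plausible
#' intermediates). Each program carries its own 15-gene signature block on
#' top of the shared marker genes, and doublet library sizes exceed the
#' 10,000-UMI QC ceiling by construction.
#'
#' @param n_cells Total cells (default 10,000).
#' @param doublet_rate Doublet fraction (default 0.03).
#' @return A `simulation_spec`.
#' @export
area_x_preset <- function(n_cells = 10000, doublet_rate = 0.03) {
  filler <- stats::setNames(rep(c(2, 5, 8, 12, 20), length.out = 470),
                            sprintf("G%03d", seq_len(470)))
  sig <- function(prefix) {
    stats::setNames(rep(6, 15), paste0(prefix, sprintf("%02d", 1:15)))
  }
  base_markers <- c(Gad2 = 0.05, Slc17a6 = 0.05, Lhx6 = 0.05, Pvalb = 0.05,
                    Sst = 0.05, Npy = 0.05, Nos1 = 0.05, Chat = 0.05,
                    Penk = 0.05, Tshz1 = 0.05, Lrig1 = 0.05, Meis2 = 0.05,
                    Ppp1r1b = 0.05, FoxP1 = 0.05, Tac1 = 0.05, Csf1r = 0.05,
                    Flt1 = 0.05, Mbp = 0.05, Pdgfra = 0.05)
  with_markers <- function(...) {
    hot <- c(...)
    out <- base_markers
    out[names(hot)] <- hot
    out
  }
  msn_markers <- with_markers(Gad2 = 8, Ppp1r1b = 8, FoxP1 = 8, Tac1 = 6,
                              Meis2 = 4)
  programs <- list(
    cell_program("MSN-direct-like", 0.34,
                 c(filler, msn_markers, sig("DIR")),
                 receptor_probs = c(0.60, 0.02, 0.06, 0.32),
                 foxp2_given_class = c(0.61, 0.21, 0.50, 0.40)),
    cell_program("MSN-indirect-like", 0.34,
                 c(filler, msn_markers, sig("IND")),
                 receptor_probs = c(0.12, 0.24, 0.30, 0.34),
                 foxp2_given_class = c(0.61, 0.21, 0.50, 0.40)),
    cell_program("PN", 0.024,
                 c(filler, with_markers(Gad2 = 6, Penk = 8, Tshz1 = 8),
                   sig("PNX"))),
    cell_program("Interneuron", 0.10,
                 c(filler, with_markers(Gad2 = 8, Pvalb = 8, Sst = 6,
                                        Lhx6 = 4), sig("INT"))),
    cell_program("Astrocyte", 0.10,
                 c(filler, with_markers(Lrig1 = 8), sig("AST"))),
    cell_program("Oligodendrocyte", 0.096,
                 c(filler, with_markers(Mbp = 12), sig("OLI")))
  )
  simulation_spec(programs, n_cells = n_cells, doublet_rate = doublet_rate)
}
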