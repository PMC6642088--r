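#!/usr/bin/env Rscript
# Compartments and loops. These are the depth-hungry analyses (the real
# libraries behind them carry ~1e8 reads), so this script simulates a
# dedicated deeper pair of libraries — amplification-free vs 12 PCR cycles —
# on a 10 Mb chromosome: A/B checkerboard recovery from the Pearson-matrix
# eigenvector (25 kb bins; coarser than the 10 kb of deep libraries to keep
# desk-scale bins populated), and aggregate peak analysis of the planted
# loops (P2LL, ZscoreLL), restricted to loops away from the diagonal.

suppressPackageStartupMessages(library(hicamp))
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

SEED <- 2024L
spec <- list(list("chr1", 1e7))
cfg0 <- sim_config(n_true_ligations = 6e5, n_sequenced = 4e5,
                   pcr_cycles = 0, seed = SEED)
cfg12 <- sim_config(n_true_ligations = 6e5, n_sequenced = 4e5,
                    pcr_cycles = 12, seed = SEED)

genome <- simulate_genome(cfg0, spec)
ligations <- simulate_true_ligations(genome, cfg0)
loops <- loops_to_bedpe(genome)
message(sprintf("deep pair: %d true ligations, %d planted loops",
                nrow(ligations), nrow(loops)))

rows <- list()
for (cyc in c(0L, 12L)) {
  cfg <- if (cyc == 0L) cfg0 else cfg12
  reads <- sequence_library(amplify(ligations, cfg), cfg)
  keep <- apply_dedup(reads, safe_mode = cyc == 0L)

  res <- 25000
  bal <- kr_balance(bin_contacts(keep, res, "chr1"))
  labels <- genome$compartment_labels$chr1[floor(seq(0, bal$n_bins - 1) * res / genome$window_bp) + 1]
  ev <- compartment_eigenvector(bal, labels = labels)
  agree <- mean(sign(ev$eigenvector) == ifelse(labels == "A", 1, -1), na.rm = TRUE)

  m10 <- bin_contacts(keep, 10000, "chr1")
  ap <- apa(m10, loops, min_separation = 80)
  pl <- per_loop_p2ll(m10, loops, min_separation = 80)
  v <- pl$p2ll[pl$usable & is.finite(pl$p2ll)]
  rows[[length(rows) + 1L]] <- data.frame(
    cycles = cyc, compartment_agreement = agree,
    p2ll = ap$p2ll, zscore_ll = ap$zscore_ll,
    per_loop_p2ll_mean = mean(v), n_loops_used = ap$n_loops_used)
  message(sprintf("cycles %2d: compartment sign agreement %.2f, P2LL %.2f (Z %.1f, %d loops), per-loop mean %.2f",
                  cyc, agree, ap$p2ll, ap$zscore_ll, ap$n_loops_used, mean(v)))
}
write.table(do.call(rbind, rows), "results/tables/compartments_apa.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message("finding: planted compartments and loops are recovered; amplification leaves compartments intact while shifting loop-pixel enrichment")
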