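#!/usr/bin/env Rscript
# Build the study's synthetic world: one genome (restriction fragments with
# 194 bp median spacing, TADs, loops, A/B compartments, GC track) and a panel
# of sequenced libraries from the same pool of true ligation events — one
# amplification-free (0 cycles) and one per PCR cycle count in {4, 8, 12, 20}.
# Writes .pairs files and ground truth under results/data/.

suppressPackageStartupMessages(library(hicamp))
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

SEED <- 2024L
CYCLES <- c(0L, 4L, 8L, 12L, 20L)
spec <- list(list("chr1", 4e6))

base_cfg <- function(cycles) {
  sim_config(n_true_ligations = 1.2e5, n_sequenced = 7e4,
             pcr_cycles = cycles, seed = SEED)
}

genome <- simulate_genome(base_cfg(0L), spec)
ligations <- simulate_true_ligations(genome, base_cfg(0L))
message(sprintf("genome: %d restriction sites, %d TADs, %d loops; %d true ligations",
                length(genome$restriction_sites$chr1), nrow(genome$tads),
                nrow(genome$loops), nrow(ligations)))

write_bed(genome$tads, "results/data/true_tads.bed")
write_bedpe(loops_to_bedpe(genome), "results/data/true_loops.bedpe")

for (cyc in CYCLES) {
  cfg <- base_cfg(cyc)
  pool <- amplify(ligations, cfg)
  reads <- sequence_library(pool, cfg)
  path <- sprintf("results/data/library_cycles%02d.pairs", cyc)
  write_pairs(reads, path)
  message(sprintf("cycles %2d: mean copy number %6.1f, %d read pairs -> %s",
                  cyc, mean(pool$copy_number), nrow(reads), path))
}
message("done: same ligation pool sequenced at five amplification levels")
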