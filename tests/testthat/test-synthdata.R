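test_that("restriction-site spacing matches the configured median", {
  cfg <- sim_config(seed = 42)
  g <- simulate_genome(cfg, list(list("chr1", 1.5e6)))
  spacing <- diff(g$restriction_sites$chr1)
  expect_gt(length(spacing), 5000)
  # exponential spacings: empirical median within 10% of the 194 bp target
  expect_lt(abs(median(spacing) - 194) / 194, 0.10)
})

test_that("genome simulation validates input and is deterministic", {
  cfg <- sim_config(seed = 5)
  expect_error(simulate_genome(cfg, list(list("chr1", 0))), "10 kb")
  expect_error(simulate_genome(cfg, list()), "empty")
  g1 <- simulate_genome(cfg, list(list("chrA", 5e5), list("chrB", 3e5)))
  g2 <- simulate_genome(cfg, list(list("chrA", 5e5), list("chrB", 3e5)))
  expect_identical(g1, g2)
  # invariants: sites strictly increasing, TADs sorted non-overlapping,
  # anchors ordered, GC in [0,1]
  for (cn in g1$chrom_names) {
    expect_true(all(diff(g1$restriction_sites[[cn]]) > 0))
    expect_true(all(g1$gc_track[[cn]] >= 0 & g1$gc_track[[cn]] <= 1))
  }
  tt <- g1$tads[g1$tads$chrom == "chrA", ]
  expect_true(all(diff(tt$start) > 0))
  expect_true(all(tt$start[-1] >= tt$end[-nrow(tt)]))
  expect_true(all(g1$loops$anchor1 < g1$loops$anchor2))
})

test_that("trans_fraction = 0 yields a purely cis library", {
  cfg <- sim_config(n_true_ligations = 2000, trans_fraction = 0, seed = 3)
  g <- simulate_genome(cfg, list(list("chr1", 5e5), list("chr2", 5e5)))
  lig <- simulate_true_ligations(g, cfg)
  expect_true(all(lig$chrom1 == lig$chrom2))
  expect_error(simulate_true_ligations(g, sim_config(n_true_ligations = 0)),
               ">= 1")
})

test_that("simulated separations follow the planted power law", {
  cfg <- sim_config(n_true_ligations = 3e4, trans_fraction = 0,
                    tad_enrichment = 1, loop_enrichment = 1,
                    compartment_strength = 1, seed = 11)
  g <- simulate_genome(cfg, list(list("chr1", 2e7)))
  lig <- simulate_true_ligations(g, cfg)
  dc <- decay_curve(lig, n_log_bins = 40, s_min = 1000)
  slope <- fit_decay_exponent(dc, c(2e3, 2e6))
  expect_gt(slope, -1.1)
  expect_lt(slope, -0.9)
})

test_that("within-TAD contacts are enriched by the configured fold", {
  cfg <- sim_config(n_true_ligations = 8e4, trans_fraction = 0,
                    tad_enrichment = 4, loop_enrichment = 1,
                    compartment_strength = 1, seed = 21)
  g <- simulate_genome(cfg, list(list("chr1", 4e6)))
  lig <- simulate_true_ligations(g, cfg)
  tads <- g$tads
  s <- abs(lig$pos2 - lig$pos1)
  t1 <- findInterval(lig$pos1, tads$start + 1)
  in1 <- t1 >= 1 & lig$pos1 <= tads$end[pmax(t1, 1)]
  t2 <- findInterval(lig$pos2, tads$start + 1)
  in2 <- t2 >= 1 & lig$pos2 <= tads$end[pmax(t2, 1)]
  same_tad <- in1 & in2 & t1 == t2
  # distance-matched strata: ratio of within- to cross-TAD density, where
  # the availability of each class at each separation is measured on an
  # unweighted reference simulation
  ref_cfg <- sim_config(n_true_ligations = 8e4, trans_fraction = 0,
                        tad_enrichment = 1, loop_enrichment = 1,
                        compartment_strength = 1, seed = 22)
  ref <- simulate_true_ligations(g, ref_cfg)
  rs <- abs(ref$pos2 - ref$pos1)
  rt1 <- findInterval(ref$pos1, tads$start + 1)
  rin1 <- rt1 >= 1 & ref$pos1 <= tads$end[pmax(rt1, 1)]
  rt2 <- findInterval(ref$pos2, tads$start + 1)
  rin2 <- rt2 >= 1 & ref$pos2 <= tads$end[pmax(rt2, 1)]
  rsame <- rin1 & rin2 & rt1 == rt2
  edges <- exp(seq(log(1000), log(2e5), length.out = 6))
  ratios <- numeric(0)
  for (b in seq_len(length(edges) - 1)) {
    k <- s >= edges[b] & s < edges[b + 1]
    rk <- rs >= edges[b] & rs < edges[b + 1]
    if (sum(k) < 500 || sum(rk & rsame) < 100 || sum(rk & !rsame) < 100) next
    obs_odds <- sum(k & same_tad) / sum(k & !same_tad)
    ref_odds <- sum(rk & rsame) / sum(rk & !rsame)
    ratios <- c(ratios, obs_odds / ref_odds)
  }
  expect_gt(length(ratios), 1)
  expect_lt(abs(mean(ratios) - 4) / 4, 0.20)
})

test_that("PCR branching process has the expected copy-number law", {
  g <- simulate_genome(sim_config(seed = 1), list(list("chr1", 5e5)))
  cfg0 <- sim_config(n_true_ligations = 2000, pcr_cycles = 0, seed = 1)
  lig <- simulate_true_ligations(g, cfg0)
  expect_true(all(amplify(lig, cfg0)$copy_number == 1L))

  # deterministic doubling: efficiency 1, no bias
  cfg1 <- sim_config(n_true_ligations = 2000, pcr_cycles = 5, pcr_efficiency = 1,
                     gc_bias_slope = 0, distance_bias_slope = 0, seed = 1)
  expect_true(all(amplify(lig, cfg1)$copy_number == 2L^5))

  # branching-process mean (1 + p)^c within 3 SE
  cfg2 <- sim_config(n_true_ligations = 1e4, pcr_cycles = 8, pcr_efficiency = 0.5,
                     gc_bias_slope = 0, distance_bias_slope = 0, seed = 2)
  lig2 <- simulate_true_ligations(simulate_genome(cfg2, list(list("chr1", 2e6))), cfg2)
  copies <- amplify(lig2, cfg2)$copy_number
  expected <- 1.5^8
  se <- sd(copies) / sqrt(length(copies))
  expect_lt(abs(mean(copies) - expected), 3 * se)

  expect_error(amplify(lig, sim_config(pcr_cycles = -1)), "count")
})

test_that("sequencing draws by copy number and emulates optical duplicates", {
  cfg <- sim_config(n_true_ligations = 5000, n_sequenced = 5000,
                    optical_dup_rate = 0, seed = 9)
  g <- simulate_genome(cfg, list(list("chr1", 2e6)))
  lig <- simulate_true_ligations(g, cfg)
  pool <- amplify(lig, cfg)
  reads <- sequence_library(pool, cfg)
  expect_equal(nrow(reads), 5000)
  # ground-truth closure: every sequenced molecule id exists in the pool
  expect_true(all(reads$mid %in% pool$mid))
  # determinism
  expect_identical(as.data.frame(reads), as.data.frame(sequence_library(pool, cfg)))
  # with optical_dup_rate = 0 near-duplicate pixels on a shared tile occur
  # only by chance: expected co-tile close pairs ~ C(n,2)/768 * pi*30^2/9e8
  same_key <- paste(reads$lane, reads$tile)
  close_pairs <- 0L
  for (k in unique(same_key)) {
    idx <- which(same_key == k)
    if (length(idx) < 2) next
    dx <- outer(reads$x[idx], reads$x[idx], "-")
    dy <- outer(reads$y[idx], reads$y[idx], "-")
    d <- sqrt(dx^2 + dy^2)
    close_pairs <- close_pairs + (sum(d < 30) - length(idx)) / 2
  }
  expect_lte(close_pairs, 3)

  cfg_od <- sim_config(n_true_ligations = 5000, n_sequenced = 5000,
                       optical_dup_rate = 0.02, seed = 9)
  reads_od <- sequence_library(pool, cfg_od)
  expect_gt(nrow(reads_od), 5000)
  extra <- reads_od[5001:nrow(reads_od), ]
  expect_true(all(extra$mid %in% pool$mid))

  expect_error(sequence_library(pool[0, ], cfg), "empty")
})

test_that("conservation: total copies with efficiency 1 equal n * 2^c", {
  cfg <- sim_config(n_true_ligations = 500, pcr_cycles = 6, pcr_efficiency = 1,
                    gc_bias_slope = 0, distance_bias_slope = 0, seed = 4)
  g <- simulate_genome(cfg, list(list("chr1", 3e5)))
  lig <- simulate_true_ligations(g, cfg)
  pool <- amplify(lig, cfg)
  expect_identical(sum(pool$copy_number), nrow(pool) * 64L)
})

test_that("identical config gives byte-identical simulated libraries", {
  cfg <- sim_config(n_true_ligations = 3000, n_sequenced = 2000,
                    pcr_cycles = 4, seed = 77)
  spec <- list(list("chr1", 8e5), list("chr2", 4e5))
  lib1 <- simulate_library(cfg, spec)
  lib2 <- simulate_library(cfg, spec)
  expect_identical(as.data.frame(lib1$reads), as.data.frame(lib2$reads))
  expect_identical(lib1$pool$copy_number, lib2$pool$copy_number)
})
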