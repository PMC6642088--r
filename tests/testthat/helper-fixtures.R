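# Fixture builders and independent oracles shared across test files.

# random read-pair table with flow-cell optics, tight position range so
# wobble clustering actually fires
random_pairs <- function(n, pos_range = 500, chroms = c("chr1", "chr2"),
                         lens = c(chr1 = 1e6, chr2 = 8e5)) {
  df <- data.frame(
    read_id = sprintf("r%05d", seq_len(n)),
    chrom1 = sample(chroms, n, replace = TRUE),
    pos1 = sample.int(pos_range, n, replace = TRUE),
    chrom2 = sample(chroms, n, replace = TRUE),
    pos2 = sample.int(pos_range, n, replace = TRUE),
    strand1 = sample(c("+", "-"), n, replace = TRUE),
    strand2 = sample(c("+", "-"), n, replace = TRUE),
    lane = sample.int(2L, n, replace = TRUE),
    tile = sample.int(3L, n, replace = TRUE),
    x = round(runif(n, 0, 2000)),
    y = round(runif(n, 0, 2000)),
    stringsAsFactors = FALSE)
  hic_pairs(df, chrom_order = chroms, chrom_lengths = lens)
}

# dense symmetric matrix -> contact_matrix
dense_to_cm <- function(M, chrom = "chr1", resolution = 25000) {
  idx <- which(upper.tri(M, diag = TRUE), arr.ind = TRUE)
  contact_matrix(chrom, resolution, nrow(M), idx[, 1] - 1L, idx[, 2] - 1L, M[idx])
}

# all-pairs O(n^2) duplicate classifier: single-linkage closure by BFS over
# the full boolean duplicate relation, then the same representative and
# optical rules, written independently of the package internals
brute_force_dedup <- function(pairs, wobble, pixel_threshold = 100) {
  df <- as.data.frame(pairs)
  n <- nrow(df)
  adj <- matrix(FALSE, n, n)
  for (a in seq_len(n)) {
    same <- df$chrom1 == df$chrom1[a] & df$chrom2 == df$chrom2[a] &
      df$strand1 == df$strand1[a] & df$strand2 == df$strand2[a] &
      abs(df$pos1 - df$pos1[a]) <= wobble & abs(df$pos2 - df$pos2[a]) <= wobble
    adj[a, ] <- same
  }
  comp <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  label <- rep("unique", n)
  for (g in seq_len(cur)) {
    mem <- which(comp == g)
    o <- mem[order(df$pos1[mem], df$pos2[mem], df$read_id[mem])]
    rep_r <- o[1]
    for (v in o[-1]) {
      same_tile <- df$lane[v] == df$lane[rep_r] && df$tile[v] == df$tile[rep_r]
      d <- sqrt((df$x[v] - df$x[rep_r])^2 + (df$y[v] - df$y[rep_r])^2)
      label[v] <- if (same_tile && d <= pixel_threshold) "optical_duplicate" else "pcr_duplicate"
    }
  }
  list(label = label, component = comp)
}

# long-run alternating Sinkhorn-Knopp oracle (row/column scalings,
# symmetrized); independent of the package's Knight-Ruiz path
sinkhorn_oracle <- function(A, n_iter = 10000L) {
  r <- rep(1, nrow(A))
  for (it in seq_len(n_iter)) {
    cc <- 1 / drop(crossprod(A, r))
    r <- 1 / drop(A %*% cc)
  }
  cc <- 1 / drop(crossprod(A, r))
  sqrt(r * cc)
}

# dense brute-force APA windowing oracle
apa_oracle <- function(D, pixels, w, corner, min_sep = 2 * w + 2) {
  n <- nrow(D)
  agg <- matrix(0, 2 * w + 1, 2 * w + 1)
  used <- 0L
  per <- numeric(0)
  for (r in seq_len(nrow(pixels))) {
    bi <- pixels$bi[r]; bj <- pixels$bj[r]
    if (is.na(bi) || bj - bi < min_sep || bi - w < 0 || bj + w > n - 1 || bi + w >= bj - w) next
    Wm <- D[(bi - w + 1):(bi + w + 1), (bj - w + 1):(bj + w + 1)]
    agg <- agg + Wm
    used <- used + 1L
    cr <- Wm[(2 * w + 2 - corner):(2 * w + 1), 1:corner]
    per <- c(per, if (mean(cr) > 0) Wm[w + 1, w + 1] / mean(cr) else NA_real_)
  }
  cr <- agg[(2 * w + 2 - corner):(2 * w + 1), 1:corner]
  list(p2ll = agg[w + 1, w + 1] / mean(cr), aggregate = agg, used = used,
       per_loop = per,
       zscore = (agg[w + 1, w + 1] - mean(cr)) / sqrt(mean((cr - mean(cr))^2)))
}

# planted-TAD contact map sampled through the full simulator, with the true
# boundary bins (interior TAD starts rounded to the bin grid); human-scale
# TAD lengths, matching the 25 kb / block-8 border-index analysis
simulate_tad_map <- function(seed, chrom_len = 4e6, resolution = 25000,
                             n_lig = 3e5, tad_enrichment = 4) {
  cfg <- sim_config(n_true_ligations = n_lig, trans_fraction = 0,
                    tad_enrichment = tad_enrichment, loop_enrichment = 1,
                    compartment_strength = 1,
                    tad_min_bp = 3e5, tad_max_bp = 6e5, seed = seed)
  g <- simulate_genome(cfg, list(list("chr1", chrom_len)))
  lig <- simulate_true_ligations(g, cfg)
  mat <- bin_contacts(lig, resolution, "chr1")
  truth <- round(g$tads$start[g$tads$start > 0] / resolution)
  list(matrix = mat, truth_bins = truth, genome = g, ligations = lig)
}
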