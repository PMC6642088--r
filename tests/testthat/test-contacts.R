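test_that("binning follows the floor((pos-1)/res) convention", {
  p <- hic_pairs(data.frame(read_id = c("a", "b"),
                            chrom1 = "chr1", pos1 = c(12000, 21000),
                            chrom2 = "chr1", pos2 = c(38000, 29000),
                            strand1 = "+", strand2 = "+"),
                 chrom_lengths = c(chr1 = 1e5))
  m <- bin_contacts(p, 10000, "chr1")
  expect_equal(m$n_bins, 10L)
  D <- as_dense(m)
  expect_equal(D[2, 4], 1)          # (12000, 38000) -> bins (1, 3)
  expect_equal(D[3, 3], 1)          # both ends in bin 2 -> diagonal
  expect_equal(sum(D), 3)           # off-diagonal entry mirrored, diagonal once
})

test_that("binned counts equal a dense brute-force histogram", {
  set.seed(61)
  n <- 2000
  p <- hic_pairs(data.frame(read_id = sprintf("r%d", 1:n),
                            chrom1 = "chr1", pos1 = sample.int(5e5, n, TRUE),
                            chrom2 = "chr1", pos2 = sample.int(5e5, n, TRUE),
                            strand1 = "+", strand2 = "+"),
                 chrom_lengths = c(chr1 = 5e5))
  res <- 25000
  m <- bin_contacts(p, res, "chr1")
  D <- as_dense(m)
  ref <- matrix(0, m$n_bins, m$n_bins)
  for (r in seq_len(n)) {
    b1 <- floor((p$pos1[r] - 1) / res) + 1
    b2 <- floor((p$pos2[r] - 1) / res) + 1
    i <- min(b1, b2); j <- max(b1, b2)
    ref[i, j] <- ref[i, j] + 1
    if (i != j) ref[j, i] <- ref[j, i] + 1
  }
  expect_equal(D, ref)
})

test_that("KR balancing solves the closed-form cases", {
  # equal row sums r: weights 1/sqrt(r)
  M <- matrix(2, 10, 10)
  bal <- kr_balance(dense_to_cm(M))
  expect_true(bal$converged)
  expect_equal(bal$weights, rep(1 / sqrt(20), 10), tolerance = 1e-6)
  # diagonal matrix: w_i = 1/sqrt(d_i)
  d <- c(1, 4, 9, 16, 25)
  bal2 <- kr_balance(dense_to_cm(diag(d)))
  expect_equal(bal2$weights, 1 / sqrt(d), tolerance = 1e-6)
})

test_that("KR balances random matrices to tolerance, matching Sinkhorn", {
  set.seed(62)
  for (rep in 1:5) {
    n <- sample(20:120, 1)
    A <- matrix(runif(n * n, 0.05, 3), n); A <- (A + t(A)) / 2
    bal <- kr_balance(dense_to_cm(A))
    expect_true(bal$converged)
    D <- as_dense(bal, balanced = TRUE)
    expect_lt(max(abs(rowSums(D) - 1)), 1e-6)
    w_oracle <- sinkhorn_oracle(A, 3000)
    expect_lt(max(abs(bal$weights - w_oracle) / w_oracle), 1e-5)
  }
})

test_that("all-zero rows are masked and NA-propagated", {
  M <- matrix(runif(64, 0.5, 2), 8); M <- (M + t(M)) / 2
  M[3, ] <- 0; M[, 3] <- 0
  bal <- kr_balance(dense_to_cm(M))
  expect_true(is.na(bal$weights[3]))
  D <- as_dense(bal, balanced = TRUE)
  expect_true(all(is.na(D[3, ])))
  expect_lt(max(abs(rowSums(D, na.rm = TRUE)[-3] - 1)), 1e-6)
})

test_that("cis/trans ratio counts pairs and flags the degenerate case", {
  df <- data.frame(read_id = sprintf("r%d", 1:29),
                   chrom1 = c(rep("chr1", 27), "chr1", "chr1"),
                   pos1 = seq(1, by = 1000, length.out = 29),
                   chrom2 = c(rep("chr1", 27), "chr2", "chr2"),
                   pos2 = seq(5e4, by = 1000, length.out = 29),
                   strand1 = "+", strand2 = "+")
  p <- hic_pairs(df, chrom_order = c("chr1", "chr2"))
  ct <- cis_trans_ratio(p)
  expect_equal(ct$ratio, 13.5)
  cis_only <- hic_pairs(df[1:27, ], chrom_order = c("chr1", "chr2"))
  ct0 <- cis_trans_ratio(cis_only)
  expect_identical(ct0$ratio, Inf)
  expect_true(ct0$flagged_infinite)
})

test_that("decay curve is a normalized density over log-spaced bins", {
  # contacts at a single separation occupy exactly one bin
  p <- hic_pairs(data.frame(read_id = sprintf("r%d", 1:50), chrom1 = "chr1",
                            pos1 = seq(1e4, by = 3000, length.out = 50),
                            chrom2 = "chr1",
                            pos2 = seq(1e4, by = 3000, length.out = 50) + 60000,
                            strand1 = "+", strand2 = "+"),
                 chrom_lengths = c(chr1 = 1e6))
  dc <- decay_curve(p, n_log_bins = 20, s_min = 1000)
  expect_equal(sum(dc$freq), 1)
  hot <- which(dc$n_pairs > 0)
  expect_length(hot, 1)
  expect_true(dc$s_lo[hot] <= 60000 && dc$s_hi[hot] > 60000)
  # a curve against itself is identically 1
  r <- decay_ratio(dc, dc)
  expect_true(all(r$ratio[dc$freq > 0] == 1))
  expect_true(all(is.na(r$ratio[dc$freq == 0])))
  # mismatched bin edges are rejected
  dc2 <- decay_curve(p, n_log_bins = 21, s_min = 1000)
  expect_error(decay_ratio(dc2, dc), "mismatched")
})

test_that("decay exponent fit is exact on noise-free power laws", {
  s <- exp(seq(log(1e3), log(1e6), length.out = 30))
  for (alpha in c(-1, -0.5)) {
    curve <- data.frame(s_lo = s, s_hi = s * 1.1, s_mid = s,
                        n_pairs = rep(1000, 30), freq = s^alpha / sum(s^alpha))
    class(curve) <- c("decay_curve", "data.frame")
    expect_equal(fit_decay_exponent(curve), alpha, tolerance = 1e-9)
  }
})

test_that("within-TAD decay restricts to pairs inside one interval", {
  tads <- data.frame(chrom = "chr1", start = c(0, 2e5), end = c(1e5, 3e5))
  df <- data.frame(read_id = sprintf("r%d", 1:3), chrom1 = "chr1",
                   pos1 = c(10000, 210000, 90000),
                   chrom2 = "chr1",
                   pos2 = c(60000, 260000, 150000),   # third crosses the gap
                   strand1 = "+", strand2 = "+")
  p <- hic_pairs(df, chrom_lengths = c(chr1 = 5e5))
  dc <- within_tad_decay(p, tads, n_log_bins = 10, s_min = 1000)
  expect_equal(sum(dc$n_pairs), 2)
})

test_that("SCC is 1 on identical and scaled maps, near 0 on independent maps", {
  set.seed(63)
  n <- 120
  M <- matrix(rpois(n * n, 4), n); M <- M + t(M)
  a <- dense_to_cm(M, resolution = 1e5)
  expect_equal(scc(a, a)$scc, 1)
  b <- dense_to_cm(2 * M, resolution = 1e5)
  expect_equal(scc(a, b)$scc, 1)
  r <- scc(a, b)
  expect_equal(r$scc, scc(b, a)$scc)
  # per-stratum identity of the weighting
  expect_equal(r$scc, sum(r$per_stratum$weight * r$per_stratum$r) /
                 sum(r$per_stratum$weight))
  hits <- 0L
  for (s in 1:8) {
    set.seed(s)
    A <- matrix(rpois(n * n, 4), n); A <- A + t(A)
    B <- matrix(rpois(n * n, 4), n); B <- B + t(B)
    v <- scc(dense_to_cm(A, resolution = 1e5), dense_to_cm(B, resolution = 1e5))$scc
    if (abs(v) < 0.1) hits <- hits + 1L
  }
  expect_gte(hits, 7L)
})

test_that("Mann-Whitney U matches closed forms and the reference implementation", {
  # exhaustive case: {1,2,3} vs {4,5,6} has U = 0, one-sided p = 1/20
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(r$u, 0)
  expect_equal(r$p_value, 1 / 20)
  expect_equal(r$method, "exact")
  # identical samples (full ties): two-sided p = 1 under the tie-corrected
  # normal approximation
  r2 <- mann_whitney_u(1:10, 1:10)
  expect_gte(r2$p_value, 0.95)
  # cross-check against stats::wilcox.test (the independent reference)
  set.seed(64)
  x <- rnorm(15); y <- rnorm(18, 0.3)
  ref <- wilcox.test(x, y, exact = TRUE)
  got <- mann_whitney_u(x, y)
  expect_equal(got$u, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  xt <- round(rnorm(40), 1); yt <- round(rnorm(35, 0.4), 1)  # ties -> normal approx
  reft <- wilcox.test(xt, yt, exact = FALSE, correct = TRUE)
  gott <- mann_whitney_u(xt, yt)
  expect_equal(gott$p_value, reft$p.value, tolerance = 1e-10)
})

test_that("GC representation compares libraries and reacts to planted GC bias", {
  set.seed(65)
  gc <- round(runif(3000, 0.25, 0.6), 3)
  mk <- function(gcv) {
    n <- length(gcv)
    hic_pairs(data.frame(read_id = sprintf("r%d", 1:n), chrom1 = "chr1",
                         pos1 = sample.int(1e6, n, TRUE), chrom2 = "chr1",
                         pos2 = sample.int(1e6, n, TRUE),
                         strand1 = "+", strand2 = "+", gc = gcv))
  }
  a <- mk(gc)
  same <- gc_representation(a, a)
  expect_true(all(same$table$ratio[same$table$frac_a > 0] == 1))
  expect_gte(same$p_value, 0.99)

  # library resampled with weight increasing in GC: ratio climbs, p small
  w <- exp(6 * gc)
  b <- mk(sample(gc, 3000, replace = TRUE, prob = w))
  biased <- gc_representation(a, b)
  expect_lt(biased$p_value, 1e-6)
  tab <- biased$table[biased$table$frac_a > 0.005, ]
  expect_gt(cor(tab$gc_lo, tab$ratio, method = "spearman"), 0.8)
})
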