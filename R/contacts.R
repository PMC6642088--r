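#' Bin cis read pairs into a contact matrix
#'
#' Bin index is `floor((pos - 1) / resolution)` (pairs positions are 1-based,
#' bins 0-based half-open); only cis pairs on `chrom` are counted; storage is
#' upper-triangle COO.
#'
#' @param pairs a [hic_pairs()] table (deduplicated per library convention).
#' @param resolution bin size, bp.
#' @param chrom chromosome to bin.
#' @param chrom_length chromosome length, bp; defaults to the `chrom_lengths`
#'   attribute of `pairs`.
#' @return a [contact_matrix()].
#' @export
bin_contacts <- function(pairs, resolution, chrom, chrom_length = NULL) {
  stopifnot(inherits(pairs, "hic_pairs"))
  if (is.null(chrom_length)) {
    lens <- attr(pairs, "chrom_lengths")
    if (is.null(lens) || !chrom %in% names(lens))
      stop("chrom_length not given and not available from the pairs table")
    chrom_length <- lens[[chrom]]
  }
  n_bins <- as.integer(ceiling(chrom_length / resolution))
  df <- as.data.frame(pairs)
  k <- df$chrom1 == chrom & df$chrom2 == chrom
  b1 <- pmin(floor((df$pos1[k] - 1) / resolution), n_bins - 1L)
  b2 <- pmin(floor((df$pos2[k] - 1) / resolution), n_bins - 1L)
  i <- pmin(b1, b2); j <- pmax(b1, b2)
  if (length(i)) {
    key <- i * n_bins + j
    tab <- table(key)
    keys <- as.numeric(names(tab))
    ii <- floor(keys / n_bins); jj <- keys - ii * n_bins
    contact_matrix(chrom, resolution, n_bins, ii, jj, as.numeric(tab))
  } else {
    contact_matrix(chrom, resolution, n_bins, integer(0), integer(0), numeric(0))
  }
}

# Knight-Ruiz balancing of a symmetric non-negative matrix (inner-outer
# Newton iteration with conjugate-gradient inner solves). Returns x with
# rowSums(diag(x) A diag(x)) = 1 when converged.
kr_bnewt <- function(A, tol = 1e-6, delta = 0.1, Delta = 3, max_iter = 5000L) {
  n <- nrow(A)
  e <- rep(1, n)
  x <- e
  g <- 0.9; etamax <- 0.1; eta <- etamax
  stop_tol <- tol * 0.5
  rt <- tol^2
  v <- x * drop(A %*% x)
  rk <- 1 - v
  rho_km1 <- drop(crossprod(rk))
  rout <- rho_km1; rold <- rout
  mvp <- 0L
  while (rout > rt && mvp < max_iter) {
    k <- 0L; y <- e
    innertol <- max(eta^2 * rout, rt)
    rho_km2 <- rho_km1
    Z <- p <- NULL
    while (rho_km1 > innertol) {
      k <- k + 1L
      if (k == 1L) {
        Z <- rk / v
        p <- Z
        rho_km1 <- drop(crossprod(rk, Z))
      }
      w <- x * drop(A %*% (x * p)) + v * p
      alpha <- rho_km1 / drop(crossprod(p, w))
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        if (delta == 0) break
        ind <- which(ap < 0)
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- which(ynew > Delta)
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- drop(crossprod(rk, Z))
      p <- Z + (rho_km1 / rho_km2) * p
      mvp <- mvp + 1L
      if (mvp >= max_iter) break
    }
    x <- x * y
    v <- x * drop(A %*% x)
    rk <- 1 - v
    rho_km1 <- drop(crossprod(rk))
    rout <- rho_km1
    mvp <- mvp + 1L
    rat <- rout / rold; rold <- rout
    res_norm <- sqrt(rout)
    eta_o <- eta
    eta <- g * rat
    if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
    eta <- max(min(eta, etamax), stop_tol / (2 * max(res_norm, .Machine$double.eps)))
  }
  list(x = x, converged = rout <= rt)
}

# symmetric Sinkhorn-Knopp scaling: alternate row/column scalings of the
# doubly-stochastic problem, symmetrized as w = sqrt(r * c)
sinkhorn_balance <- function(A, n_iter = 10000L, tol = 1e-12) {
  n <- nrow(A)
  r <- rep(1, n)
  for (it in seq_len(n_iter)) {
    c_ <- 1 / drop(crossprod(A, r))
    r_new <- 1 / drop(A %*% c_)
    if (max(abs(r_new - r) / pmax(r_new, .Machine$double.eps)) < tol) { r <- r_new; break }
    r <- r_new
  }
  c_ <- 1 / drop(crossprod(A, r))
  sqrt(r * c_)
}

# connected components of the support graph of a symmetric matrix (BFS)
support_components <- function(A) {
  n <- nrow(A)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(A[v, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Knight-Ruiz balancing of a contact matrix
#'
#' Finds per-bin weights `w` such that `diag(w) M diag(w)` has every
#' unmasked row (and by symmetry column) sum equal to 1 within `tol` — the
#' matrix normalization applied before all downstream map analyses. All-zero
#' rows are masked out before balancing (weight `NA`). The solver is the
#' Knight-Ruiz inner-outer Newton iteration; if it stagnates, a symmetric
#' Sinkhorn iteration is run as a fallback. A non-balanceable matrix
#' (reducible support) yields `converged = FALSE` with the weights of the
#' largest balanceable support component and a warning.
#'
#' @param m a [contact_matrix()] with raw counts.
#' @param tol maximum allowed deviation of unmasked row sums from 1.
#' @param max_iter matrix-vector-product budget for the KR solver.
#' @return the matrix with a `weights` vector (NA on masked bins),
#'   `balanced = TRUE`, and attribute-like field `converged`.
#' @export
kr_balance <- function(m, tol = 1e-6, max_iter = 5000L) {
  stopifnot(inherits(m, "contact_matrix"))
  D <- as_dense(m)
  n <- nrow(D)
  active <- which(rowSums(D) > 0)
  weights <- rep(NA_real_, n)
  converged <- FALSE
  if (length(active) >= 2L) {
    A <- D[active, active, drop = FALSE]
    fit <- kr_bnewt(A, tol = tol, max_iter = max_iter)
    x <- fit$x
    if (!fit$converged) {
      x <- sinkhorn_balance(A)
      dev <- max(abs(x * drop(A %*% x) - 1))
      fit$converged <- is.finite(dev) && dev <= tol
    }
    if (!fit$converged) {
      comp <- support_components(A)
      main <- which(comp == which.max(tabulate(comp)))
      if (length(main) < length(comp)) {
        warning("matrix support is reducible; balancing largest component only")
        x <- rep(NA_real_, length(active))
        sub <- A[main, main, drop = FALSE]
        fit2 <- kr_bnewt(sub, tol = tol, max_iter = max_iter)
        xs <- if (fit2$converged) fit2$x else sinkhorn_balance(sub)
        x[main] <- xs
        dev <- max(abs(xs * drop(sub %*% xs) - 1))
        fit$converged <- is.finite(dev) && dev <= tol
      } else {
        warning("KR balancing did not converge to tolerance")
      }
    }
    weights[active] <- x
    converged <- fit$converged
  } else if (length(active) == 1L) {
    d <- D[active, active]
    if (d > 0) { weights[active] <- 1 / sqrt(d); converged <- TRUE }
  }
  m$weights <- weights
  m$balanced <- TRUE
  m$converged <- converged
  m
}

#' Cis/trans ratio of a library
#'
#' The ratio of cis to trans unique paired reads — a standard proxy for
#' Hi-C library quality.
#'
#' @param pairs a [hic_pairs()] table (already deduplicated).
#' @return list `n_cis`, `n_trans`, `ratio` (Inf flagged when no trans pairs).
#' @export
cis_trans_ratio <- function(pairs) {
  stopifnot(inherits(pairs, "hic_pairs"))
  cis <- sum(pairs$chrom1 == pairs$chrom2)
  trans <- nrow(pairs) - cis
  list(n_cis = cis, n_trans = trans,
       ratio = if (trans == 0) Inf else cis / trans,
       flagged_infinite = trans == 0)
}

# total measure of locus pairs per log-distance bin: for each segment of
# length L and bin [a, b), integral of (L - s) ds over s in [a, min(b, L)]
locus_pair_measure <- function(edges, seg_lengths) {
  k <- length(edges) - 1L
  out <- numeric(k)
  for (b in seq_len(k)) {
    a <- edges[b]; bb <- edges[b + 1L]
    hi <- pmin(bb, seg_lengths)
    valid <- hi > a
    out[b] <- sum((seg_lengths[valid] * (hi[valid] - a) - (hi[valid]^2 - a^2) / 2))
  }
  out
}

#' Distance-decay curve P(s)
#'
#' Histograms cis pair separations in log-spaced bins, divides each bin count
#' by the genomic measure of locus pairs at that separation (diagonal-length
#' normalization, so the curve is a density over possible pairs), and
#' normalizes the result to sum to 1 across bins.
#'
#' @param pairs a [hic_pairs()] table.
#' @param n_log_bins number of log-spaced distance bins.
#' @param s_min,s_max distance range, bp; `s_max` defaults to the longest
#'   chromosome/segment length.
#' @param segments optional data.frame `chrom, start, end` restricting the
#'   analysis: only pairs with both ends in a single segment count, and the
#'   locus-pair normalization uses segment lengths (used for within-TAD
#'   decay). Default: whole chromosomes.
#' @return a `decay_curve` data.frame: `s_lo`, `s_hi`, `s_mid`, `n_pairs`,
#'   `freq` (sums to 1).
#' @export
decay_curve <- function(pairs, n_log_bins = 50, s_min = 1000, s_max = NULL,
                        segments = NULL) {
  stopifnot(inherits(pairs, "hic_pairs"))
  df <- as.data.frame(pairs)
  cis <- df$chrom1 == df$chrom2
  s <- abs(df$pos2 - df$pos1)[cis]
  if (is.null(segments)) {
    lens <- attr(pairs, "chrom_lengths")
    if (is.null(lens)) lens <- tapply(pmax(df$pos1, df$pos2), df$chrom1, max)
    seg_lengths <- as.numeric(lens)
  } else {
    ch <- df$chrom1[cis]; p1 <- df$pos1[cis]; p2 <- df$pos2[cis]
    inside <- rep(FALSE, length(p1))
    for (cc in unique(segments$chrom)) {
      seg <- segments[segments$chrom == cc, , drop = FALSE]
      k <- which(ch == cc)
      if (!length(k)) next
      i1 <- findInterval(p1[k], seg$start + 1)    # BED half-open, pairs 1-based
      ok <- i1 >= 1 & p1[k] <= seg$end[pmax(i1, 1L)]
      i2 <- findInterval(p2[k], seg$start + 1)
      ok <- ok & i2 >= 1 & p2[k] <= seg$end[pmax(i2, 1L)] & i1 == i2
      inside[k] <- ok
    }
    s <- s[inside]
    seg_lengths <- as.numeric(segments$end - segments$start)
  }
  if (is.null(s_max)) s_max <- max(seg_lengths)
  edges <- exp(seq(log(s_min), log(s_max), length.out = n_log_bins + 1L))
  s <- s[s >= s_min & s <= s_max]
  cnt <- tabulate(findInterval(s, edges, rightmost.closed = TRUE),
                  nbins = n_log_bins)
  meas <- locus_pair_measure(edges, seg_lengths)
  freq <- ifelse(meas > 0, cnt / meas, 0)
  tot <- sum(freq)
  if (tot > 0) freq <- freq / tot
  out <- data.frame(s_lo = edges[-length(edges)], s_hi = edges[-1],
                    s_mid = sqrt(edges[-length(edges)] * edges[-1]),
                    n_pairs = cnt, freq = freq)
  class(out) <- c("decay_curve", "data.frame")
  out
}

#' Within-TAD distance-decay curve
#'
#' [decay_curve()] restricted to pairs whose two ends fall inside the same
#' TAD interval, normalized by the locus pairs available within TADs.
#'
#' @param pairs a [hic_pairs()] table.
#' @param tads data.frame `chrom, start, end` (0-based half-open, bp).
#' @param ... passed to [decay_curve()].
#' @return a `decay_curve`.
#' @export
within_tad_decay <- function(pairs, tads, ...) {
  decay_curve(pairs, segments = tads, ...)
}

#' Fit the distance-decay exponent
#'
#' Least-squares slope of `log10(freq)` on `log10(s)` over the requested
#' distance range, weighted by the pair count per bin. A slope near -1 is the
#' fractal-globule expectation; near -0.5 the mitotic expectation.
#'
#' @param curve a [decay_curve()].
#' @param s_range length-2 distance range (bp) over which to fit.
#' @return the fitted slope (numeric scalar).
#' @export
fit_decay_exponent <- function(curve, s_range = range(curve$s_mid)) {
  k <- curve$s_mid >= s_range[1] & curve$s_mid <= s_range[2] &
    curve$freq > 0 & curve$n_pairs > 0
  if (sum(k) < 3L) stop("fewer than 3 usable bins in s_range")
  fit <- stats::lm(log10(freq) ~ log10(s_mid), data = curve[k, ],
                   weights = curve$n_pairs[k])
  unname(stats::coef(fit)[2])
}

#' Ratio of two decay curves
#'
#' Per-bin frequency ratio `curve / reference` — the decay-ratio comparison
#' of an amplified library against its amplification-free reference. Bins
#' where the reference frequency is zero are masked (`NA`).
#'
#' @param curve,reference [decay_curve()]s on identical bin edges.
#' @return data.frame `s_mid`, `ratio`.
#' @export
decay_ratio <- function(curve, reference) {
  if (nrow(curve) != nrow(reference) ||
      max(abs(log(curve$s_lo / reference$s_lo))) > 1e-9)
    stop("decay curves have mismatched bin edges")
  ratio <- ifelse(reference$freq > 0, curve$freq / reference$freq, NA_real_)
  data.frame(s_mid = curve$s_mid, ratio = ratio)
}

# box-filter smoothing with edge renormalization (summed-area table)
smooth_matrix <- function(M, h) {
  if (h <= 0) return(M)
  n <- nrow(M)
  S <- matrix(0, n + 1L, n + 1L)
  S[-1, -1] <- t(apply(apply(M, 2, cumsum), 1, cumsum))
  idx <- seq_len(n)
  lo <- pmax(idx - h, 1L); hi <- pmin(idx + h, n)
  out <- matrix(0, n, n)
  for (r in idx) {
    r1 <- lo[r]; r2 <- hi[r]
    sums <- S[r2 + 1L, hi + 1L] - S[r1, hi + 1L] - S[r2 + 1L, lo] + S[r1, lo]
    out[r, ] <- sums / ((r2 - r1 + 1L) * (hi - lo + 1L))
  }
  out
}

#' Stratum-adjusted correlation coefficient between two contact maps
#'
#' Reproducibility statistic for Hi-C: matrices are (optionally) smoothed
#' with a `(2h+1)`-bin mean filter, a Pearson correlation `r_k` is computed
#' within each genomic-distance stratum `k`, and the strata are combined with
#' weights `N_k * sd_a,k * sd_b,k`:
#' `SCC = sum_k w_k r_k / sum_k w_k`. Strata with zero variance in either
#' map are skipped.
#'
#' @param a,b [contact_matrix()]s on the same chromosome, resolution and bin
#'   count (raw counts).
#' @param max_distance largest genomic distance (bp) included.
#' @param smooth_h half-width of the mean filter in bins (0 = none; 1 is the
#'   conventional choice at 100 kb resolution).
#' @return an `scc_result` list: `scc`, `per_stratum` data.frame.
#' @export
scc <- function(a, b, max_distance = 5e6, smooth_h = 1L) {
  stopifnot(inherits(a, "contact_matrix"), inherits(b, "contact_matrix"))
  if (a$n_bins != b$n_bins || a$resolution != b$resolution)
    stop("matrices must share resolution and bin count")
  A <- smooth_matrix(as_dense(a), smooth_h)
  B <- smooth_matrix(as_dense(b), smooth_h)
  n <- a$n_bins
  K <- min(n - 1L, floor(max_distance / a$resolution))
  rows <- vector("list", K + 1L)
  for (k in 0:K) {
    ii <- seq_len(n - k)
    va <- A[cbind(ii, ii + k)]
    vb <- B[cbind(ii, ii + k)]
    sa <- stats::sd(va); sb <- stats::sd(vb)
    if (length(va) < 2L || !is.finite(sa) || !is.finite(sb) || sa == 0 || sb == 0) next
    r <- stats::cor(va, vb)
    rows[[k + 1L]] <- data.frame(stratum = k, distance = k * a$resolution,
                                 r = r, n = length(va), weight = length(va) * sa * sb)
  }
  per <- do.call(rbind, rows)
  if (is.null(per) || nrow(per) == 0L) stop("no usable strata")
  res <- list(scc = sum(per$weight * per$r) / sum(per$weight), per_stratum = per)
  class(res) <- "scc_result"
  res
}

#' @export
print.scc_result <- function(x, ...) {
  cat(sprintf("<scc_result> SCC = %.6f over %d strata\n", x$scc, nrow(x$per_stratum)))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples; exact null distribution when both
#' sample sizes are at most 20 and there are no ties, otherwise the normal
#' approximation with tie correction and continuity correction. `U` counts
#' pairs where x exceeds y (plus half-ties).
#'
#' @param x,y numeric samples.
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (x vs y).
#' @return list `u`, `p_value`, `method`.
#' @export
mann_whitney_u <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  n1 <- as.numeric(length(x)); n2 <- as.numeric(length(y))
  if (n1 == 0 || n2 == 0) stop("empty sample")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # pairs with x > y (+ ties/2)
  ties <- as.numeric(table(c(x, y)))
  exact <- n1 <= 20 && n2 <= 20 && all(ties == 1)
  if (exact) {
    p <- switch(alternative,
      less = stats::pwilcox(u, n1, n2),
      greater = stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE),
      two.sided = {
        if (u > n1 * n2 / 2)
          min(1, 2 * stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE))
        else
          min(1, 2 * stats::pwilcox(u, n1, n2))
      })
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    N <- n1 + n2
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_term))
    z <- u - mu
    cc <- switch(alternative, two.sided = sign(z) * 0.5, less = -0.5, greater = 0.5)
    z <- (z - cc) / sigma
    p <- switch(alternative,
      less = stats::pnorm(z),
      greater = stats::pnorm(z, lower.tail = FALSE),
      two.sided = 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
    p <- min(1, p)
    method <- "normal approximation with tie correction"
  }
  list(u = u, p_value = p, method = method)
}

#' GC-content representation of one library against another
#'
#' Compares the fragment-pair GC distributions of two libraries: per-GC-bin
#' fractions in each library, their ratio (library b over reference a), and a
#' two-sided Mann-Whitney U test on the per-pair GC values. Amplified
#' libraries typically show under-representation of low-GC and
#' over-representation of high-GC fragment pairs relative to an
#' amplification-free reference.
#'
#' @param pairs_a reference library (must carry a `gc` column).
#' @param pairs_b comparison library.
#' @param gc_bin_width width of GC bins (fraction; default 0.02 = 2
#'   percentage points).
#' @return list: `table` (per-bin fractions and ratio), `u`, `p_value`.
#' @export
gc_representation <- function(pairs_a, pairs_b, gc_bin_width = 0.02) {
  for (p in list(pairs_a, pairs_b))
    if (!"gc" %in% names(p) || anyNA(p$gc)) stop("records must carry a gc field")
  ga <- pairs_a$gc; gb <- pairs_b$gc
  edges <- seq(0, 1, by = gc_bin_width)
  nb <- length(edges) - 1L
  fa <- tabulate(findInterval(ga, edges, rightmost.closed = TRUE), nbins = nb) / length(ga)
  fb <- tabulate(findInterval(gb, edges, rightmost.closed = TRUE), nbins = nb) / length(gb)
  tab <- data.frame(gc_lo = edges[-length(edges)], gc_hi = edges[-1],
                    frac_a = fa, frac_b = fb,
                    ratio = ifelse(fa > 0, fb / fa, NA_real_))
  mw <- mann_whitney_u(gb, ga, alternative = "two.sided")
  list(table = tab, u = mw$u, p_value = mw$p_value, method = mw$method)
}
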