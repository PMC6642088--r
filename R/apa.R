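#' Aggregate peak analysis of chromatin loops
#'
#' Stacks the `(2w+1) x (2w+1)` raw-count window centered on each loop pixel
#' (rows follow the upstream anchor, columns the downstream anchor, so the
#' lower-left `c x c` corner of the window is the short-distance background
#' corner) and reports
#' `P2LL` — the central pixel of the aggregate over the mean of its
#' lower-left corner — and `ZscoreLL` — the central pixel's Z-score against
#' the corner pixels (population SD). Loops whose window would cross the
#' diagonal (anchor separation below `min_separation`) or exit the matrix
#' are skipped and counted.
#'
#' @param m a [contact_matrix()] (raw counts by default).
#' @param loops BEDPE-style data.frame `chrom1,start1,end1,chrom2,start2,end2`
#'   of cis loop anchors; the loop pixel is the bin of each anchor midpoint.
#' @param w window half-width in bins (default 10).
#' @param c corner size in bins (default 6).
#' @param min_separation minimum anchor separation in bins (default `2w + 2`
#'   so windows never touch the diagonal).
#' @param balanced use balanced counts instead of raw.
#' @return an `apa_result` list: `aggregate`, `p2ll`, `zscore_ll` (NA when the
#'   corner has zero variance), `n_loops_used`, `n_loops_skipped`.
#' @export
apa <- function(m, loops, w = 10L, c = 6L, min_separation = NULL, balanced = FALSE) {
  stopifnot(inherits(m, "contact_matrix"))
  w <- as.integer(w); c <- as.integer(c)
  if (is.null(min_separation)) min_separation <- 2L * w + 2L
  D <- as_dense(m, balanced = balanced)
  n <- m$n_bins
  px <- loop_pixels(m, loops)
  agg <- matrix(0, 2L * w + 1L, 2L * w + 1L)
  used <- 0L; skipped <- 0L
  for (r in seq_len(nrow(px))) {
    bi <- px$bi[r]; bj <- px$bj[r]
    if (is.na(bi) || bj - bi < min_separation ||
        bi - w < 0L || bj + w > n - 1L || bi + w >= bj - w) {
      skipped <- skipped + 1L
      next
    }
    Wm <- D[(bi - w + 1L):(bi + w + 1L), (bj - w + 1L):(bj + w + 1L)]
    if (anyNA(Wm)) { skipped <- skipped + 1L; next }
    agg <- agg + Wm
    used <- used + 1L
  }
  if (used == 0L) stop("no usable loops")
  res <- apa_stats(agg, w, c)
  out <- list(aggregate = agg, w = w, corner_size = c,
              p2ll = res$p2ll, zscore_ll = res$zscore_ll,
              n_loops_used = used, n_loops_skipped = skipped)
  class(out) <- "apa_result"
  out
}

# loop anchor midpoints -> 0-based bins of a contact matrix (NA off-chrom)
loop_pixels <- function(m, loops) {
  mid1 <- (loops$start1 + loops$end1) / 2
  mid2 <- (loops$start2 + loops$end2) / 2
  on_chrom <- loops$chrom1 == m$chrom & loops$chrom2 == m$chrom
  b1 <- ifelse(on_chrom, floor(mid1 / m$resolution), NA_real_)
  b2 <- ifelse(on_chrom, floor(mid2 / m$resolution), NA_real_)
  data.frame(bi = pmin(b1, b2), bj = pmax(b1, b2))
}

# P2LL / ZscoreLL geometry on a (2w+1)^2 window: center pixel vs the
# lower-left (short-distance) c x c corner = max rows x min columns
apa_stats <- function(W, w, c) {
  center <- W[w + 1L, w + 1L]
  nr <- nrow(W)
  corner <- W[(nr - c + 1L):nr, 1:c]
  mu <- mean(corner)
  sd_pop <- sqrt(mean((corner - mu)^2))
  list(p2ll = if (mu > 0) center / mu else NA_real_,
       zscore_ll = if (sd_pop > 0) (center - mu) / sd_pop else NA_real_)
}

#' @export
print.apa_result <- function(x, ...) {
  cat(sprintf("<apa_result> P2LL = %.3f, ZscoreLL = %s, %d loops used (%d skipped)\n",
              x$p2ll, ifelse(is.na(x$zscore_ll), "NA", sprintf("%.2f", x$zscore_ll)),
              x$n_loops_used, x$n_loops_skipped))
  invisible(x)
}

#' Per-loop P2LL values
#'
#' The same window geometry as [apa()] applied loop by loop without
#' aggregation: each loop's pixel divided by the mean of the lower-left
#' corner of its own window.
#'
#' @inheritParams apa
#' @return data.frame with the loop anchors, `p2ll` and `usable` flag;
#'   empty input gives an empty result.
#' @export
per_loop_p2ll <- function(m, loops, w = 10L, c = 6L, min_separation = NULL,
                          balanced = FALSE) {
  stopifnot(inherits(m, "contact_matrix"))
  w <- as.integer(w); c <- as.integer(c)
  if (is.null(min_separation)) min_separation <- 2L * w + 2L
  if (nrow(loops) == 0L)
    return(cbind(loops, data.frame(p2ll = numeric(0), usable = logical(0))))
  D <- as_dense(m, balanced = balanced)
  n <- m$n_bins
  px <- loop_pixels(m, loops)
  p2ll <- rep(NA_real_, nrow(loops))
  usable <- rep(FALSE, nrow(loops))
  for (r in seq_len(nrow(loops))) {
    bi <- px$bi[r]; bj <- px$bj[r]
    if (is.na(bi) || bj - bi < min_separation ||
        bi - w < 0L || bj + w > n - 1L || bi + w >= bj - w) next
    Wm <- D[(bi - w + 1L):(bi + w + 1L), (bj - w + 1L):(bj + w + 1L)]
    if (anyNA(Wm)) next
    st <- apa_stats(Wm, w, c)
    p2ll[r] <- st$p2ll
    usable[r] <- TRUE
  }
  cbind(loops, data.frame(p2ll = p2ll, usable = usable))
}
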