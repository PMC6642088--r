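#' Border-strength index of a contact map
#'
#' For each candidate boundary position `b` (between 0-based bins `b-1` and
#' `b`) and moving block size `k`, sums the within-block contacts of the
#' upstream block `[b-k, b)` (A) and downstream block `[b, b+k)` (A'),
#' excluding diagonal self-contacts, and the cross-block contacts B between
#' the two blocks, and reports `BI(b) = (A + A') / B`. Computed on the
#' balanced map; positions whose window contains masked bins, or where
#' `B = 0`, are masked (`NA`). On a uniform map the index is the closed-form
#' `2 * choose(k,2) / k^2` (0.875 at k = 8); TAD boundaries appear as peaks.
#'
#' @param m a balanced [contact_matrix()] (or any matrix with `raw = TRUE`).
#' @param k moving block size in bins (default 8, the 25-kb convention).
#' @param raw allow computing on raw counts.
#' @return a `border_track` data.frame: `boundary` (0-based bin index of the
#'   boundary), `value`; attributes `resolution`, `k`, `n_bins`.
#' @export
border_index <- function(m, k = 8L, raw = FALSE) {
  stopifnot(inherits(m, "contact_matrix"))
  if (!raw && !m$balanced)
    stop("matrix is not balanced; run kr_balance() or pass raw = TRUE")
  n <- m$n_bins
  if (n <= 2L * k) stop("need n_bins > 2k")
  D <- as_dense(m, balanced = !raw && !is.null(m$weights))
  bs <- k:(n - k)
  vals <- rep(NA_real_, length(bs))
  for (t in seq_along(bs)) {
    b <- bs[t]
    up <- (b - k + 1L):b          # 1-based rows of the upstream block
    dn <- (b + 1L):(b + k)
    Mu <- D[up, up]; Md <- D[dn, dn]; Mb <- D[up, dn]
    if (anyNA(Mu) || anyNA(Md) || anyNA(Mb)) next
    A <- (sum(Mu) - sum(diag(Mu))) / 2
    Ap <- (sum(Md) - sum(diag(Md))) / 2
    B <- sum(Mb)
    if (B > 0) vals[t] <- (A + Ap) / B
  }
  out <- data.frame(boundary = bs, value = vals)
  attr(out, "resolution") <- m$resolution
  attr(out, "k") <- k
  attr(out, "n_bins") <- n
  class(out) <- c("border_track", "data.frame")
  out
}

# topographic prominence of a peak at index i in values v (NA-safe)
peak_prominence <- function(v, i) {
  h <- v[i]
  base <- -Inf
  for (dir in c(-1L, 1L)) {
    j <- i + dir
    side_min <- h
    while (j >= 1L && j <= length(v)) {
      x <- v[j]
      if (!is.na(x)) {
        if (x > h) break
        if (x < side_min) side_min <- x
      }
      j <- j + dir
    }
    if (side_min > base) base <- side_min
  }
  h - base
}

#' Call TAD borders as peaks of the border-strength track
#'
#' Local maxima of the border index, filtered by a prominence floor and
#' thinned so accepted peaks are at least `min_peak_distance` bins apart
#' (higher peaks win; ties broken toward higher prominence, then the smaller
#' index). Masked positions are never peaks.
#'
#' @param track a [border_index()] track.
#' @param min_peak_distance minimum bin separation between accepted borders
#'   (default 10, the standard peak-calling setting).
#' @param min_prominence prominence floor; default
#'   `0.1 * (quantile(value, .9) - median(value))`, a scale-free floor that
#'   suppresses noise peaks on flat tracks.
#' @return integer vector of boundary positions (0-based bins), sorted.
#' @export
call_borders <- function(track, min_peak_distance = 10L, min_prominence = NULL) {
  stopifnot(inherits(track, "border_track"))
  v <- track$value
  n <- length(v)
  if (n == 0L) return(integer(0))
  if (is.null(min_prominence)) {
    fin <- v[is.finite(v)]
    min_prominence <- if (length(fin) >= 2L)
      0.1 * (stats::quantile(fin, 0.9, names = FALSE) - stats::median(fin)) else 0
  }
  left <- c(NA, v[-n]); right <- c(v[-1], NA)
  is_peak <- !is.na(v) &
    (is.na(left) | v > left) &
    (is.na(right) | v >= right)
  # plateau: keep only the leftmost point of a run of equal values
  cand <- which(is_peak)
  if (length(cand) == 0L) return(integer(0))
  prom <- vapply(cand, function(i) peak_prominence(v, i), 0)
  keep <- prom >= min_prominence & prom > 0
  cand <- cand[keep]; prom <- prom[keep]
  if (length(cand) == 0L) return(integer(0))
  o <- order(-v[cand], -prom, cand)
  accepted <- integer(0)
  for (i in o) {
    b <- track$boundary[cand[i]]
    if (all(abs(b - accepted) >= min_peak_distance)) accepted <- c(accepted, b)
  }
  sort(accepted)
}

#' Convert borders to a set of TAD intervals
#'
#' Successive borders delimit TADs; chromosome ends close the first and last
#' interval. With no borders the whole chromosome is one interval.
#'
#' @param borders 0-based boundary bin positions.
#' @param n_bins number of bins on the chromosome.
#' @param resolution bin size, bp.
#' @param chrom chromosome name.
#' @param chrom_length optional bp length to clip the final interval.
#' @return data.frame `chrom`, `start`, `end` (bp, 0-based half-open),
#'   non-overlapping and sorted.
#' @export
borders_to_tads <- function(borders, n_bins, resolution, chrom = "chr",
                            chrom_length = NULL) {
  cuts <- sort(unique(c(0, borders, n_bins)))
  starts <- cuts[-length(cuts)] * resolution
  ends <- cuts[-1] * resolution
  if (!is.null(chrom_length)) ends <- pmin(ends, chrom_length)
  data.frame(chrom = chrom, start = starts, end = ends, stringsAsFactors = FALSE)
}

#' Reciprocal-overlap matching of two TAD sets
#'
#' A pair of intervals matches iff their overlap spans at least
#' `reciprocal` of EACH interval's length (the `-f 0.9 -F 0.9` convention).
#' Each interval is matched at most once, greedily by overlap length with
#' ties broken toward the leftmost pair.
#'
#' @param tads_a,tads_b data.frames `chrom`, `start`, `end`.
#' @param reciprocal required overlap fraction of each interval (default 0.9).
#' @return list: `shared` (data.frame of matched index pairs `a`, `b` and
#'   `overlap`), `a_only`, `b_only` (row indices), and counts.
#' @export
tad_overlap <- function(tads_a, tads_b, reciprocal = 0.9) {
  na <- nrow(tads_a); nb <- nrow(tads_b)
  cand <- NULL
  if (na > 0L && nb > 0L) {
    grid <- expand.grid(a = seq_len(na), b = seq_len(nb))
    same <- tads_a$chrom[grid$a] == tads_b$chrom[grid$b]
    grid <- grid[same, , drop = FALSE]
    if (nrow(grid)) {
      ov <- pmin(tads_a$end[grid$a], tads_b$end[grid$b]) -
        pmax(tads_a$start[grid$a], tads_b$start[grid$b])
      la <- tads_a$end[grid$a] - tads_a$start[grid$a]
      lb <- tads_b$end[grid$b] - tads_b$start[grid$b]
      ok <- ov >= reciprocal * la & ov >= reciprocal * lb & ov > 0
      grid <- grid[ok, , drop = FALSE]; ov <- ov[ok]
      if (nrow(grid)) {
        o <- order(-ov, tads_a$start[grid$a], tads_b$start[grid$b])
        used_a <- logical(na); used_b <- logical(nb)
        keep <- logical(nrow(grid))
        for (i in o) {
          if (!used_a[grid$a[i]] && !used_b[grid$b[i]]) {
            keep[i] <- TRUE
            used_a[grid$a[i]] <- TRUE
            used_b[grid$b[i]] <- TRUE
          }
        }
        cand <- data.frame(a = grid$a[keep], b = grid$b[keep], overlap = ov[keep])
      }
    }
  }
  if (is.null(cand)) cand <- data.frame(a = integer(0), b = integer(0), overlap = numeric(0))
  list(shared = cand,
       a_only = setdiff(seq_len(na), cand$a),
       b_only = setdiff(seq_len(nb), cand$b),
       n_shared = nrow(cand), n_a_only = na - nrow(cand), n_b_only = nb - nrow(cand))
}

# A/A'/B sums of a 2f x 2f boundary-centered matrix (boundary at the center)
corner_sums <- function(W, f) {
  up <- seq_len(f); dn <- f + seq_len(f)
  Mu <- W[up, up]; Md <- W[dn, dn]
  A <- (sum(Mu) - sum(diag(Mu))) / 2
  Ap <- (sum(Md) - sum(diag(Md))) / 2
  B <- sum(W[up, dn])
  c(A = A, Ap = Ap, B = B)
}

#' Aggregate contact map around TAD borders and its (A + A')/B ratio
#'
#' Extracts the `2f x 2f` submatrix centered on each border, sums the
#' submatrices (borders within `f` bins of the chromosome ends, or with
#' masked bins in the window, are skipped), and computes the ratio of
#' flanking-TAD contacts (A + A') to inter-TAD contacts (B) on the aggregate
#' with the same block geometry as [border_index()] at `k = f`. Strong,
#' well-placed borders give a high ratio; distance-dependent amplification
#' bias lowers it.
#'
#' @param m a balanced [contact_matrix()] (or `raw = TRUE`).
#' @param borders 0-based boundary bin positions.
#' @param flank_bins `f`, the half-width of the aggregated window (default 8).
#' @param raw compute on raw counts.
#' @return list: `aggregate` (2f x 2f matrix), `ratio`, `n_borders_used`.
#' @export
aggregate_border_ratio <- function(m, borders, flank_bins = 8L, raw = FALSE) {
  stopifnot(inherits(m, "contact_matrix"))
  f <- as.integer(flank_bins)
  D <- as_dense(m, balanced = !raw && !is.null(m$weights))
  n <- m$n_bins
  agg <- matrix(0, 2L * f, 2L * f)
  used <- 0L
  for (b in borders) {
    if (b < f || b > n - f) next
    idx <- (b - f + 1L):(b + f)
    W <- D[idx, idx]
    if (anyNA(W)) next
    agg <- agg + W
    used <- used + 1L
  }
  if (used == 0L) stop("no usable borders (all within flank_bins of ends or masked)")
  cs <- corner_sums(agg, f)
  if (cs[["B"]] == 0) stop("aggregate inter-TAD sum is zero")
  list(aggregate = agg, ratio = (cs[["A"]] + cs[["Ap"]]) / cs[["B"]],
       n_borders_used = used)
}
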