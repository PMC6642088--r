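#' Observed/expected transform of a balanced contact map
#'
#' Divides every entry by the mean of its genomic-distance stratum, removing
#' the distance decay so the checkerboard compartment signal dominates.
#' Strata with zero mean (or only masked bins) are masked.
#'
#' @param m a balanced [contact_matrix()] (or `raw = TRUE`).
#' @param raw compute on raw counts.
#' @return dense `n_bins x n_bins` observed/expected matrix (NA = masked).
#' @export
observed_expected <- function(m, raw = FALSE) {
  stopifnot(inherits(m, "contact_matrix"))
  if (!raw && !m$balanced)
    stop("matrix is not balanced; run kr_balance() or pass raw = TRUE")
  D <- as_dense(m, balanced = !raw && !is.null(m$weights))
  n <- nrow(D)
  for (k in 0:(n - 1L)) {
    ii <- seq_len(n - k)
    v <- D[cbind(ii, ii + k)]
    mu <- mean(v, na.rm = TRUE)
    oe <- if (is.finite(mu) && mu > 0) v / mu else rep(NA_real_, length(v))
    D[cbind(ii, ii + k)] <- oe
    D[cbind(ii + k, ii)] <- oe
  }
  D
}

#' A/B compartment eigenvector
#'
#' Computes the Pearson correlation matrix of the observed/expected map and
#' returns the eigenvector of its largest-magnitude eigenvalue; the sign of
#' each bin's entry encodes its compartment (A vs B). The global sign is
#' oriented so the vector correlates positively with a per-bin GC track when
#' one is supplied, else so the first A-labelled ground-truth bin is
#' positive, else so the first nonzero entry is positive.
#'
#' @param m a balanced [contact_matrix()].
#' @param gc optional per-bin GC values used to orient the sign.
#' @param labels optional per-bin ground-truth labels ("A"/"B") used to
#'   orient the sign when `gc` is absent.
#' @param raw compute on raw counts.
#' @return list: `eigenvector` (length `n_bins`, NA on masked bins),
#'   `eigenvalue`, `masked` (bin indices, 1-based), `residual`
#'   (`||Cv - lambda v|| / ||v||`).
#' @export
compartment_eigenvector <- function(m, gc = NULL, labels = NULL, raw = FALSE) {
  OE <- observed_expected(m, raw = raw)
  n <- nrow(OE)
  col_ok <- vapply(seq_len(n), function(j) {
    v <- OE[, j]
    s <- stats::sd(v, na.rm = TRUE)
    sum(!is.na(v)) >= 3L && is.finite(s) && s > 0
  }, TRUE)
  masked <- which(!col_ok)
  if (length(masked) > n / 2)
    stop("more than 50% of bins are masked or degenerate; compartment call unreliable")
  act <- which(col_ok)
  C <- stats::cor(OE[act, act, drop = FALSE], use = "pairwise.complete.obs")
  C[!is.finite(C)] <- 0
  eg <- eigen(C, symmetric = TRUE)
  lead <- which.max(abs(eg$values))
  v <- eg$vectors[, lead]
  lambda <- eg$values[lead]
  residual <- sqrt(sum((C %*% v - lambda * v)^2)) / sqrt(sum(v^2))

  full <- rep(NA_real_, n)
  full[act] <- v
  sgn <- 0
  if (!is.null(gc)) {
    r <- suppressWarnings(stats::cor(full, gc, use = "pairwise.complete.obs"))
    if (is.finite(r) && r != 0) sgn <- sign(r)
  }
  if (sgn == 0 && !is.null(labels)) {
    firstA <- which(labels == "A" & !is.na(full))[1]
    if (!is.na(firstA) && full[firstA] != 0) sgn <- sign(full[firstA])
  }
  if (sgn == 0) {
    nz <- which(full != 0 & !is.na(full))[1]
    sgn <- if (!is.na(nz)) sign(full[nz]) else 1
  }
  list(eigenvector = sgn * full, eigenvalue = lambda,
       masked = masked, residual = residual)
}
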