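#' Estimate library complexity from unique and total pair counts
#'
#' Lander-Waterman / equal-abundance model: sequencing `n_total` pairs from a
#' library of `C` distinct molecules yields
#' `E[n_unique] = C * (1 - exp(-n_total / C))` unique pairs. The estimator
#' inverts this by bracketed bisection, expanding the upper bracket
#' geometrically from `n_unique`. When `n_unique == n_total` no finite
#' solution exists (no saturation observed) and `c_hat = Inf` is returned
#' with `converged = FALSE`. PCR-amplified libraries violate the
#' equal-abundance assumption; the resulting downward bias of `c_hat` is the
#' quantity of interest, not an error to correct. Optical duplicates must be
#' excluded from both counts before calling.
#'
#' @param n_total sequenced (non-optical) pair count.
#' @param n_unique distinct pairs after deduplication.
#' @param tol relative tolerance of the bisection (default 1e-6).
#' @return a `complexity_estimate` list: `n_total`, `n_unique`, `c_hat`,
#'   `converged`.
#' @export
estimate_complexity <- function(n_total, n_unique, tol = 1e-6) {
  if (n_unique <= 0 || n_total <= 0) stop("counts must be positive")
  if (n_unique > n_total) stop("n_unique cannot exceed n_total")
  out <- list(n_total = n_total, n_unique = n_unique)
  if (n_unique == n_total) {
    out$c_hat <- Inf
    out$converged <- FALSE
    class(out) <- "complexity_estimate"
    return(out)
  }
  f <- function(C) C * (1 - exp(-n_total / C)) - n_unique  # increasing in C
  lo <- n_unique
  hi <- 2 * n_unique
  while (f(hi) < 0) {
    lo <- hi
    hi <- 2 * hi
    if (hi > 1e18) {  # numerically saturation-free
      out$c_hat <- Inf; out$converged <- FALSE
      class(out) <- "complexity_estimate"
      return(out)
    }
  }
  while ((hi - lo) / hi > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  out$c_hat <- (lo + hi) / 2
  out$converged <- TRUE
  class(out) <- "complexity_estimate"
  out
}

#' @export
print.complexity_estimate <- function(x, ...) {
  cat(sprintf("<complexity_estimate> n_total=%g n_unique=%g c_hat=%s (%s)\n",
              x$n_total, x$n_unique, format(x$c_hat, digits = 6),
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}
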