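#' Comparison report for an amplification-free vs amplified library pair
#'
#' Runs the full analysis battery on two libraries — duplicate
#' classification and percentages, depth histogram, library complexity,
#' cis/trans ratio, distance-decay curves and the amplified/reference decay
#' ratio (with its crossing point), GC representation, binned matrices with
#' KR balancing, border-strength track, border calling, TAD construction and
#' reciprocal overlap, the aggregate (A+A')/B border ratio, SCC between the
#' two maps, and (when loops are supplied) APA — and writes a
#' machine-readable JSON report plus a human-readable TSV summary. Every
#' statistic in the report is the return value of one exported module
#' function; any stage failure aborts with the stage name.
#'
#' @param config a list with entries:
#'   \describe{
#'     \item{safe_pairs, amp_pairs}{`hic_pairs` objects or `.pairs` paths;
#'       `safe` is the amplification-free reference.}
#'     \item{chrom}{chromosome analysed for map statistics (default: first).}
#'     \item{resolution}{map resolution, bp (default 25000).}
#'     \item{scc_resolution}{resolution for SCC (default 100000).}
#'     \item{wobble, optical_pixel_threshold}{dedup parameters.}
#'     \item{n_log_bins, s_min}{decay-curve parameters.}
#'     \item{border_k, min_peak_distance, flank_bins}{domain parameters.}
#'     \item{loops}{optional BEDPE data.frame or path.}
#'     \item{apa_w, apa_c}{APA window parameters.}
#'     \item{out_json, out_tsv}{optional output paths.}
#'   }
#' @return the report list, invisibly if written to file.
#' @export
run_report <- function(config) {
  req <- c("safe_pairs", "amp_pairs")
  miss <- setdiff(req, names(config))
  if (length(miss)) stop("report config is missing: ", paste(miss, collapse = ", "))
  cfg <- utils::modifyList(list(
    chrom = NULL, resolution = 25000, scc_resolution = 1e5,
    wobble = 4, optical_pixel_threshold = 100,
    n_log_bins = 40, s_min = 1000,
    border_k = 8L, min_peak_distance = 10L, flank_bins = 8L,
    loops = NULL, apa_w = 10L, apa_c = 6L,
    out_json = NULL, out_tsv = NULL), config)

  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e)
      stop(sprintf("report stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
  }
  load_pairs <- function(x) if (inherits(x, "hic_pairs")) x else read_pairs(x)
  safe <- stage("load_safe", load_pairs(cfg$safe_pairs))
  amp <- stage("load_amp", load_pairs(cfg$amp_pairs))
  if (is.null(cfg$chrom)) cfg$chrom <- attr(safe, "chrom_order")[1]
  if (!is.null(cfg$loops) && !is.data.frame(cfg$loops))
    cfg$loops <- stage("load_loops", read_bedpe(cfg$loops))

  params <- dedup_params(cfg$wobble, cfg$optical_pixel_threshold)
  per_library <- function(pairs, safe_mode) {
    dup <- classify_duplicates(pairs, params)
    stats <- dedup_statistics(dup)
    hist <- duplication_depth_histogram(dup)
    n_non_optical <- stats$n_total - stats$n_optical_dup
    cx <- estimate_complexity(n_non_optical, stats$n_unique)
    valid <- apply_dedup(pairs, dup, safe_mode = safe_mode)
    ct <- cis_trans_ratio(valid)
    list(dup = stats, depth_histogram = hist,
         complexity = list(c_hat = cx$c_hat, converged = cx$converged),
         cis_trans = ct, valid = valid)
  }
  safe_res <- stage("dedup_safe", per_library(safe, safe_mode = TRUE))
  amp_res <- stage("dedup_amp", per_library(amp, safe_mode = FALSE))

  dc_safe <- stage("decay_safe", decay_curve(safe_res$valid, cfg$n_log_bins, cfg$s_min))
  dc_amp <- stage("decay_amp", decay_curve(amp_res$valid, cfg$n_log_bins, cfg$s_min))
  dr <- stage("decay_ratio", decay_ratio(dc_amp, dc_safe))
  ok <- !is.na(dr$ratio) & dr$ratio > 0
  crossing <- NA_real_
  if (any(ok)) {
    below <- which(ok & dr$ratio < 1)
    above <- which(ok & dr$ratio > 1)
    if (length(below) && length(above) && min(below) < max(above)) {
      k <- above[above > min(below)]
      if (length(k)) crossing <- dr$s_mid[min(k)]
    }
  }
  gc_rep <- if ("gc" %in% names(safe) && "gc" %in% names(amp))
    stage("gc_representation", gc_representation(safe_res$valid, amp_res$valid)) else NULL

  domain_side <- function(valid) {
    mat <- bin_contacts(valid, cfg$resolution, cfg$chrom)
    bal <- kr_balance(mat)
    track <- border_index(bal, k = cfg$border_k)
    borders <- call_borders(track, cfg$min_peak_distance)
    tads <- borders_to_tads(borders, mat$n_bins, cfg$resolution, cfg$chrom)
    agg <- if (length(borders))
      aggregate_border_ratio(bal, borders, cfg$flank_bins) else NULL
    list(matrix = mat, balanced = bal, track = track, borders = borders,
         tads = tads, aggregate = agg)
  }
  dom_safe <- stage("domains_safe", domain_side(safe_res$valid))
  dom_amp <- stage("domains_amp", domain_side(amp_res$valid))
  overlap <- stage("tad_overlap", tad_overlap(dom_safe$tads, dom_amp$tads))

  scc_res <- stage("scc", {
    a <- bin_contacts(safe_res$valid, cfg$scc_resolution, cfg$chrom)
    b <- bin_contacts(amp_res$valid, cfg$scc_resolution, cfg$chrom)
    scc(a, b)
  })

  apa_res <- NULL
  if (!is.null(cfg$loops)) {
    apa_res <- stage("apa", {
      a <- apa(dom_safe$matrix, cfg$loops, cfg$apa_w, cfg$apa_c)
      b <- apa(dom_amp$matrix, cfg$loops, cfg$apa_w, cfg$apa_c)
      list(safe = list(p2ll = a$p2ll, zscore_ll = a$zscore_ll, n_loops = a$n_loops_used),
           amp = list(p2ll = b$p2ll, zscore_ll = b$zscore_ll, n_loops = b$n_loops_used))
    })
  }

  strip <- function(x) x[setdiff(names(x), "valid")]
  report <- list(
    parameters = cfg[c("chrom", "resolution", "scc_resolution", "wobble",
                       "optical_pixel_threshold", "n_log_bins", "s_min",
                       "border_k", "min_peak_distance", "flank_bins")],
    safe = strip(safe_res), amplified = strip(amp_res),
    decay = list(curve_safe = dc_safe, curve_amplified = dc_amp,
                 ratio = dr, crossing_bp = crossing),
    gc = if (!is.null(gc_rep)) list(u = gc_rep$u, p_value = gc_rep$p_value) else NULL,
    domains = list(
      n_tads_safe = nrow(dom_safe$tads), n_tads_amplified = nrow(dom_amp$tads),
      n_shared = overlap$n_shared,
      n_safe_only = overlap$n_a_only, n_amplified_only = overlap$n_b_only,
      aggregate_border_ratio_safe = if (!is.null(dom_safe$aggregate)) dom_safe$aggregate$ratio else NA,
      aggregate_border_ratio_amplified = if (!is.null(dom_amp$aggregate)) dom_amp$aggregate$ratio else NA),
    scc = scc_res$scc,
    apa = apa_res)

  if (!is.null(cfg$out_json)) {
    jsonlite::write_json(report, cfg$out_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null", force = TRUE)
  }
  if (!is.null(cfg$out_tsv)) {
    rows <- data.frame(
      statistic = c("pct_unique", "pct_pcr_dup", "pct_optical_dup",
                    "complexity_c_hat", "cis_trans_ratio", "n_tads",
                    "aggregate_border_ratio"),
      safe = c(safe_res$dup$pct_unique, safe_res$dup$pct_pcr_dup,
               safe_res$dup$pct_optical_dup, safe_res$complexity$c_hat,
               safe_res$cis_trans$ratio, nrow(dom_safe$tads),
               report$domains$aggregate_border_ratio_safe),
      amplified = c(amp_res$dup$pct_unique, amp_res$dup$pct_pcr_dup,
                    amp_res$dup$pct_optical_dup, amp_res$complexity$c_hat,
                    amp_res$cis_trans$ratio, nrow(dom_amp$tads),
                    report$domains$aggregate_border_ratio_amplified))
    utils::write.table(rows, cfg$out_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(cfg$out_json) || !is.null(cfg$out_tsv)) invisible(report) else report
}
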