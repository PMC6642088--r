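#' Simulation configuration
#'
#' Collects every tunable of the synthetic Hi-C library generator in one
#' validated list. Defaults describe a small amplification-free library of a
#' DpnII-digested genome: contact probability decays as \eqn{s^{-1}} (the
#' fractal-globule regime), roughly 1 trans pair per 13.5 cis pairs, 4-fold
#' within-TAD enrichment, 5-fold loop-pixel enrichment, 2-fold same-compartment
#' enrichment, and no PCR amplification. The PCR model amplifies each molecule
#' through `pcr_cycles` rounds of a branching process in which a copy
#' duplicates with probability
#' \deqn{p_i = \mathrm{clamp}\{p \cdot (1 + b_{gc}(gc_i - 0.5)) \cdot
#'       (1 + b_d(\log_{10} s_i - \mu)),\ 0,\ 1\}}
#' where \eqn{p} is `pcr_efficiency`, \eqn{\mu} the library-mean
#' \eqn{\log_{10}} separation, and trans pairs take distance factor 1.
#'
#' @param decay_exponent power-law exponent of cis contact probability vs
#'   separation (dimensionless, default -1).
#' @param trans_fraction probability a ligation joins two chromosomes
#'   (default 0.069, i.e. cis/trans near 13.5).
#' @param tad_enrichment fold enrichment of within-TAD over distance-matched
#'   cross-TAD contacts (>= 1).
#' @param loop_enrichment fold enrichment at planted loop pixels (>= 1).
#' @param compartment_strength fold enrichment of same-label compartment
#'   contacts (>= 1).
#' @param n_true_ligations number of independent background ligation events.
#' @param pcr_cycles PCR amplification cycles (0 = amplification-free).
#' @param pcr_efficiency per-cycle duplication probability before bias terms.
#' @param gc_bias_slope linear GC dependence of PCR efficiency.
#' @param distance_bias_slope linear log10-distance dependence of PCR
#'   efficiency; positive values favour long-range ligations.
#' @param n_sequenced read pairs drawn from the amplified pool.
#' @param optical_dup_rate probability a sequenced pair is re-read as an
#'   optical duplicate (same tile, nearby pixels).
#' @param optical_pixel_sigma pixel scale of the optical-duplicate offset.
#' @param fragment_median_bp target median restriction-fragment length
#'   (default 194 bp, the DpnII genome-wide median).
#' @param s_min_bp smallest cis separation drawn from the power law
#'   (default 1 kb).
#' @param tad_min_bp,tad_max_bp TAD lengths are drawn uniformly in this range.
#' @param compartment_window_bp width of the fixed A/B compartment windows and
#'   of the GC track windows.
#' @param compartment_block_windows number of consecutive windows sharing one
#'   compartment label (checkerboard block size).
#' @param loop_radius_bp half-width of the planted loop pixel.
#' @param n_loops_per_mb planted loop density.
#' @param gc_mean,gc_sd mean and spread of the per-window GC track.
#' @param seed integer seed; every stochastic stage derives its stream from it.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(decay_exponent = -1.0,
                       trans_fraction = 0.069,
                       tad_enrichment = 4,
                       loop_enrichment = 5,
                       compartment_strength = 2,
                       n_true_ligations = 1e5,
                       pcr_cycles = 0L,
                       pcr_efficiency = 0.7,
                       gc_bias_slope = 0.5,
                       distance_bias_slope = 0.1,
                       n_sequenced = 1e5,
                       optical_dup_rate = 0.005,
                       optical_pixel_sigma = 10,
                       fragment_median_bp = 194,
                       s_min_bp = 1000,
                       tad_min_bp = 2e5,
                       tad_max_bp = 4e5,
                       compartment_window_bp = 1e4,
                       compartment_block_windows = 10L,
                       loop_radius_bp = 5000,
                       n_loops_per_mb = 5,
                       gc_mean = 0.42,
                       gc_sd = 0.08,
                       seed = 1L) {
  cfg <- list(
    decay_exponent = decay_exponent,
    trans_fraction = trans_fraction,
    tad_enrichment = tad_enrichment,
    loop_enrichment = loop_enrichment,
    compartment_strength = compartment_strength,
    n_true_ligations = n_true_ligations,
    pcr_cycles = as.integer(pcr_cycles),
    pcr_efficiency = pcr_efficiency,
    gc_bias_slope = gc_bias_slope,
    distance_bias_slope = distance_bias_slope,
    n_sequenced = n_sequenced,
    optical_dup_rate = optical_dup_rate,
    optical_pixel_sigma = optical_pixel_sigma,
    fragment_median_bp = fragment_median_bp,
    s_min_bp = s_min_bp,
    tad_min_bp = tad_min_bp,
    tad_max_bp = tad_max_bp,
    compartment_window_bp = compartment_window_bp,
    compartment_block_windows = as.integer(compartment_block_windows),
    loop_radius_bp = loop_radius_bp,
    n_loops_per_mb = n_loops_per_mb,
    gc_mean = gc_mean,
    gc_sd = gc_sd,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  probs <- c("trans_fraction", "pcr_efficiency", "optical_dup_rate")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("`%s` must be a probability in [0, 1]", p), call. = FALSE)
  }
  folds <- c("tad_enrichment", "loop_enrichment", "compartment_strength")
  for (p in folds) {
    if (cfg[[p]] < 1)
      stop(sprintf("`%s` must be a fold >= 1", p), call. = FALSE)
  }
  counts <- c("n_true_ligations", "pcr_cycles", "n_sequenced")
  for (p in counts) {
    if (is.na(cfg[[p]]) || cfg[[p]] < 0)
      stop(sprintf("`%s` must be a count >= 0", p), call. = FALSE)
  }
  if (cfg$fragment_median_bp <= 0) stop("`fragment_median_bp` must be positive", call. = FALSE)
  if (cfg$s_min_bp <= 0) stop("`s_min_bp` must be positive", call. = FALSE)
  if (cfg$tad_max_bp < cfg$tad_min_bp) stop("`tad_max_bp` < `tad_min_bp`", call. = FALSE)
  invisible(cfg)
}

# Derive an independent 32-bit RNG seed for a named simulation stage so that
# each stage is deterministic given the config alone, not the call order.
stage_seed <- function(seed, stage) {
  offset <- c(genome = 11L, ligations = 23L, amplify = 37L, sequence = 51L,
              saturation = 67L)[[stage]]
  (as.integer(seed) + offset) %% .Machine$integer.max
}
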