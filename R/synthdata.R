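#' Simulate a genome model for Hi-C library synthesis
#'
#' Builds a genome with restriction sites, TADs, loops, A/B compartment
#' labels, and a GC track. Restriction-fragment lengths are i.i.d.
#' exponential with rate `log(2) / fragment_median_bp`, so the median spacing
#' matches the configured target (194 bp by default, the genome-wide DpnII
#' median). TADs tile each chromosome end to end with lengths drawn uniformly
#' in `[tad_min_bp, tad_max_bp]`; loops are planted between random TAD-scale
#' anchor pairs; compartment labels alternate A/B in blocks of
#' `compartment_block_windows` fixed-width windows; GC per window is drawn
#' from a beta distribution with mean `gc_mean` and spread `gc_sd`.
#'
#' @param config a [sim_config()].
#' @param chrom_spec list (or data.frame) of chromosome `name` and `length`
#'   in bp; lengths must be at least 10 kb.
#' @return a `genome_model` list: `chrom_names`, `chrom_lengths` (named),
#'   `restriction_sites` (named list of sorted positions), `tads`, `loops`
#'   (data.frames), `compartment_labels` and `gc_track` (named lists of
#'   per-window vectors), `window_bp`.
#' @export
simulate_genome <- function(config, chrom_spec) {
  stopifnot(inherits(config, "sim_config"))
  if (is.data.frame(chrom_spec)) {
    chrom_names <- as.character(chrom_spec$name)
    chrom_lengths <- as.numeric(chrom_spec$length)
  } else {
    chrom_names <- vapply(chrom_spec, function(x) as.character(x[[1]]), "")
    chrom_lengths <- vapply(chrom_spec, function(x) as.numeric(x[[2]]), 0)
  }
  if (length(chrom_names) == 0L) stop("empty chromosome specification")
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths < 1e4))
    stop("chromosome lengths must be >= 10 kb")
  names(chrom_lengths) <- chrom_names

  set.seed(stage_seed(config$seed, "genome"))
  rate <- log(2) / config$fragment_median_bp
  win <- config$compartment_window_bp

  restriction_sites <- list(); tad_list <- list(); loop_list <- list()
  labels <- list(); gc_track <- list()
  for (cn in chrom_names) {
    L <- chrom_lengths[[cn]]
    # exponential spacings; draw ~20% extra then cumulate past L
    n_exp <- ceiling(L * rate * 1.2) + 50L
    pos <- cumsum(stats::rexp(n_exp, rate))
    while (pos[length(pos)] < L) pos <- c(pos, pos[length(pos)] + cumsum(stats::rexp(n_exp, rate)))
    sites <- round(pos[pos < L])
    sites <- unique(sites[sites >= 1])
    restriction_sites[[cn]] <- sites

    # TADs tile the chromosome
    lens <- numeric(0); total <- 0
    while (total < L) {
      l <- stats::runif(1, config$tad_min_bp, config$tad_max_bp)
      lens <- c(lens, l); total <- total + l
    }
    starts <- c(0, cumsum(lens))[seq_along(lens)]
    ends <- pmin(starts + lens, L)
    keep <- ends - starts >= config$tad_min_bp / 2
    tad_list[[cn]] <- data.frame(chrom = cn, start = round(starts[keep]),
                                 end = round(ends[keep]), stringsAsFactors = FALSE)

    # loops: anchors separated by a TAD-to-multi-TAD scale distance, snapped
    # to centers of 2r-wide windows so each loop occupies one pixel at
    # resolution 2 * loop_radius_bp
    r <- config$loop_radius_bp
    n_loops <- max(1L, round(config$n_loops_per_mb * L / 1e6))
    sep <- stats::runif(n_loops, 2 * r + config$s_min_bp,
                        pmax(4 * config$tad_max_bp, 0.2 * L))
    a1 <- stats::runif(n_loops, r, pmax(L - sep - r, r + 1))
    a2 <- pmin(a1 + sep, L - r)
    snap <- function(a) floor(a / (2 * r)) * (2 * r) + r
    a1 <- snap(a1); a2 <- snap(a2)
    ok <- a2 > a1 + 2 * r
    loop_list[[cn]] <- data.frame(chrom = cn, anchor1 = a1[ok], anchor2 = a2[ok],
                                  stringsAsFactors = FALSE)

    n_win <- ceiling(L / win)
    block <- config$compartment_block_windows
    lab <- rep(rep(c("A", "B"), length.out = ceiling(n_win / block)), each = block)[seq_len(n_win)]
    labels[[cn]] <- lab
    shape <- config$gc_mean * (1 - config$gc_mean) / config$gc_sd^2 - 1
    gc_track[[cn]] <- stats::rbeta(n_win, config$gc_mean * shape, (1 - config$gc_mean) * shape)
  }

  g <- list(chrom_names = chrom_names, chrom_lengths = chrom_lengths,
            restriction_sites = restriction_sites,
            tads = do.call(rbind, tad_list),
            loops = do.call(rbind, loop_list),
            compartment_labels = labels, gc_track = gc_track,
            window_bp = win)
  rownames(g$tads) <- NULL; rownames(g$loops) <- NULL
  class(g) <- "genome_model"
  g
}

# nearest restriction site for each position (vectorized, one chromosome)
snap_to_sites <- function(pos, sites) {
  idx <- findInterval(pos, sites)
  lo <- sites[pmax(idx, 1L)]
  hi <- sites[pmin(idx + 1L, length(sites))]
  ifelse(idx == 0L, hi, ifelse(pos - lo <= hi - pos, lo, hi))
}

# per-position compartment label / gc lookup
window_index <- function(pos, win) pmin(pmax(floor((pos - 1) / win) + 1L, 1L), .Machine$integer.max)

# vectorized per-window track lookup across chromosomes
track_lookup <- function(track, chrom, pos, win) {
  out <- rep(track[[1]][NA_integer_], length(pos))
  for (cc in unique(chrom)) {
    k <- chrom == cc
    tr <- track[[cc]]
    out[k] <- tr[pmin(window_index(pos[k], win), length(tr))]
  }
  out
}

# sample separations with density proportional to s^alpha on [s_min, s_max]
sample_powerlaw <- function(n, alpha, s_min, s_max) {
  u <- stats::runif(n)
  if (abs(alpha + 1) < 1e-9) {
    s_min * (s_max / s_min)^u
  } else {
    a1 <- alpha + 1
    (s_min^a1 + u * (s_max^a1 - s_min^a1))^(1 / a1)
  }
}

# TAD interval index containing each position (0 if none); tads for ONE chrom
tad_index <- function(pos, tads) {
  if (nrow(tads) == 0L) return(integer(length(pos)))
  idx <- findInterval(pos, tads$start)
  inside <- idx >= 1L & pos <= tads$end[pmax(idx, 1L)] & pos > tads$start[pmax(idx, 1L)]
  ifelse(inside, idx, 0L)
}

#' Simulate true (pre-amplification) ligation events
#'
#' Draws independent ligation products from the configured genome: cis
#' separations follow a power law with exponent `decay_exponent` on
#' `[s_min_bp, L]`; candidate pairs inside one TAD, or joining same-label
#' compartment windows, are up-weighted by `tad_enrichment` and
#' `compartment_strength` via rejection sampling (so the weighted density is
#' sampled exactly and every accepted record is an independent molecule);
#' trans pairs occur with probability `trans_fraction`. Loop pixels are then
#' enriched `loop_enrichment`-fold by planting extra reads calibrated to the
#' observed background count at each loop (so the fold is relative to the
#' local expected signal); the planted extras mean the returned set can
#' slightly exceed `n_true_ligations` records. Each end is snapped to its
#' nearest restriction site; each record carries the mean window GC of its
#' two ends and a unique `mid` (true molecule id).
#'
#' @param genome a `genome_model` from [simulate_genome()].
#' @param config the [sim_config()] used to build the genome.
#' @return a `hic_pairs` data.frame (see [hic_pairs()]).
#' @export
simulate_true_ligations <- function(genome, config) {
  stopifnot(inherits(genome, "genome_model"), inherits(config, "sim_config"))
  n <- config$n_true_ligations
  if (n < 1) stop("n_true_ligations must be >= 1")
  set.seed(stage_seed(config$seed, "ligations"))

  chroms <- genome$chrom_names
  lens <- genome$chrom_lengths
  win <- genome$window_bp
  w_max_cis <- config$tad_enrichment * config$compartment_strength
  w_max_trans <- config$compartment_strength
  tads_by_chrom <- split(genome$tads, genome$tads$chrom)

  comp_weight <- function(c1, p1, c2, p2) {
    lab1 <- track_lookup(genome$compartment_labels, c1, p1, win)
    lab2 <- track_lookup(genome$compartment_labels, c2, p2, win)
    ifelse(!is.na(lab1) & !is.na(lab2) & lab1 == lab2, config$compartment_strength, 1)
  }

  # class quotas first (so trans_fraction is exact in distribution), then
  # rejection sampling within each class draws exactly from the weighted
  # density without duplicating molecules
  n_trans <- if (length(chroms) > 1L) stats::rbinom(1, n, config$trans_fraction) else 0L
  n_cis <- n - n_trans

  sample_cis <- function(target) {
    acc <- list(); n_acc <- 0L
    batch <- max(2048L, ceiling(target * 1.2))
    while (n_acc < target) {
      m <- batch
      c1 <- sample(chroms, m, replace = TRUE, prob = lens)
      l1 <- lens[c1]
      s <- sample_powerlaw(m, config$decay_exponent, config$s_min_bp, pmin(l1 - 1, max(lens)))
      s <- pmin(s, l1 - 1)
      p1 <- floor(stats::runif(m) * (l1 - s)) + 1
      p2 <- p1 + round(s)
      w <- comp_weight(c1, p1, c1, p2)
      for (cc in unique(c1)) {
        k <- which(c1 == cc)
        td <- tads_by_chrom[[cc]]
        if (is.null(td) || nrow(td) == 0L) next
        t1 <- tad_index(p1[k], td); t2 <- tad_index(p2[k], td)
        same_tad <- t1 > 0L & t1 == t2
        w[k[same_tad]] <- w[k[same_tad]] * config$tad_enrichment
      }
      keep <- stats::runif(m) < w / w_max_cis
      if (any(keep)) {
        acc[[length(acc) + 1L]] <- data.frame(
          chrom1 = c1[keep], pos1 = p1[keep], chrom2 = c1[keep], pos2 = p2[keep],
          stringsAsFactors = FALSE)
        n_acc <- n_acc + sum(keep)
      }
      batch <- max(2048L, ceiling((target - n_acc) * 1.3 / max(mean(keep), 0.05)))
    }
    do.call(rbind, acc)[seq_len(target), , drop = FALSE]
  }

  sample_trans <- function(target) {
    if (target == 0L) return(NULL)
    acc <- list(); n_acc <- 0L
    batch <- max(1024L, ceiling(target * 1.2))
    while (n_acc < target) {
      m <- batch
      c1 <- sample(chroms, m, replace = TRUE, prob = lens)
      c2 <- vapply(c1, function(cc) {
        others <- setdiff(chroms, cc)
        if (length(others) == 1L) others else sample(others, 1L, prob = lens[others])
      }, "")
      p1 <- floor(stats::runif(m) * (lens[c1] - 1)) + 1
      p2 <- floor(stats::runif(m) * (lens[c2] - 1)) + 1
      w <- comp_weight(c1, p1, c2, p2)
      keep <- stats::runif(m) < w / w_max_trans
      if (any(keep)) {
        acc[[length(acc) + 1L]] <- data.frame(
          chrom1 = c1[keep], pos1 = p1[keep], chrom2 = c2[keep], pos2 = p2[keep],
          stringsAsFactors = FALSE)
        n_acc <- n_acc + sum(keep)
      }
      batch <- max(1024L, ceiling((target - n_acc) * 1.3 / max(mean(keep), 0.05)))
    }
    do.call(rbind, acc)[seq_len(target), , drop = FALSE]
  }

  df <- rbind(sample_cis(n_cis), sample_trans(n_trans))

  # loop planting: the fold is relative to the expected background count at
  # the loop pixel, estimated from a scaled-up neighborhood (counting hits in
  # a window R >> r and rescaling by the area ratio keeps the estimate stable
  # at desk-scale coverage, since p1 is locally uniform and the decay varies
  # slowly over R)
  lp <- genome$loops
  if (!is.null(lp) && nrow(lp) > 0L && config$loop_enrichment > 1) {
    r <- config$loop_radius_bp
    extras <- vector("list", nrow(lp))
    cis_df <- df[df$chrom1 == df$chrom2, , drop = FALSE]
    for (i in seq_len(nrow(lp))) {
      cc <- lp$chrom[i]; a1 <- lp$anchor1[i]; a2 <- lp$anchor2[i]
      sub <- cis_df[cis_df$chrom1 == cc, , drop = FALSE]
      R <- max(r, min(20 * r, (a2 - a1) / 3, a1, lens[[cc]] - a2))
      hits <- sum(abs(sub$pos1 - a1) <= R & abs(sub$pos2 - a2) <= R)
      lambda <- hits * (r / R)^2
      n_extra <- stats::rpois(1, (config$loop_enrichment - 1) * lambda)
      if (n_extra > 0L) {
        extras[[i]] <- data.frame(
          chrom1 = cc,
          pos1 = round(stats::runif(n_extra, a1 - r + 1, a1 + r)),
          chrom2 = cc,
          pos2 = round(stats::runif(n_extra, a2 - r + 1, a2 + r)),
          stringsAsFactors = FALSE)
      }
    }
    extras <- do.call(rbind, extras)
    if (!is.null(extras) && nrow(extras) > 0L) df <- rbind(df, extras)
  }

  # snap ends to restriction sites; attach strands, gc, molecule ids
  for (cc in unique(c(df$chrom1, df$chrom2))) {
    sites <- genome$restriction_sites[[cc]]
    k1 <- df$chrom1 == cc
    df$pos1[k1] <- snap_to_sites(df$pos1[k1], sites)
    k2 <- df$chrom2 == cc
    df$pos2[k2] <- snap_to_sites(df$pos2[k2], sites)
  }
  df$pos1 <- pmax(df$pos1, 1); df$pos2 <- pmax(df$pos2, 1)
  nr <- nrow(df)
  df$strand1 <- sample(c("+", "-"), nr, replace = TRUE)
  df$strand2 <- sample(c("+", "-"), nr, replace = TRUE)
  gc1 <- track_lookup(genome$gc_track, df$chrom1, df$pos1, win)
  gc2 <- track_lookup(genome$gc_track, df$chrom2, df$pos2, win)
  df$gc <- round((gc1 + gc2) / 2, 4)
  df$read_id <- sprintf("L%08d", seq_len(nr))
  df$mid <- df$read_id

  hic_pairs(df, chrom_order = chroms, chrom_lengths = lens)
}

#' Amplify a ligation library by a PCR branching process
#'
#' Each molecule independently undergoes `pcr_cycles` rounds; in each round
#' every existing copy duplicates with probability
#' `clamp(pcr_efficiency * (1 + gc_bias_slope*(gc - 0.5)) *
#' (1 + distance_bias_slope*(log10(s) - mu)), 0, 1)`, where `mu` is the
#' library-mean log10 cis separation and trans pairs take distance factor 1.
#' With efficiency 1 and no bias every copy number is exactly `2^cycles`.
#'
#' @param ligations a `hic_pairs` table of true molecules.
#' @param config a [sim_config()].
#' @return a `molecule_pool`: the input records plus a `copy_number` column.
#' @export
amplify <- function(ligations, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$pcr_cycles < 0) stop("pcr_cycles must be >= 0")
  pool <- as.data.frame(ligations)
  n <- nrow(pool)
  if (n == 0L) stop("empty ligation set")
  set.seed(stage_seed(config$seed, "amplify"))

  cis <- pool$chrom1 == pool$chrom2
  s <- abs(pool$pos2 - pool$pos1)
  mu <- if (any(cis)) mean(log10(pmax(s[cis], 1))) else 0
  dist_factor <- ifelse(cis, 1 + config$distance_bias_slope * (log10(pmax(s, 1)) - mu), 1)
  gc <- if (!is.null(pool$gc)) pool$gc else rep(0.5, n)
  p <- config$pcr_efficiency * (1 + config$gc_bias_slope * (gc - 0.5)) * dist_factor
  p <- pmin(pmax(p, 0), 1)

  copies <- rep(1L, n)
  if (config$pcr_cycles > 0L) {
    for (cyc in seq_len(config$pcr_cycles)) {
      copies <- copies + stats::rbinom(n, copies, p)
    }
  }
  pool$copy_number <- copies
  attr(pool, "chrom_order") <- attr(ligations, "chrom_order")
  attr(pool, "chrom_lengths") <- attr(ligations, "chrom_lengths")
  class(pool) <- c("molecule_pool", "data.frame")
  pool
}

#' Sequence read pairs from an amplified molecule pool
#'
#' Draws `n_sequenced` records with replacement, probability proportional to
#' copy number, assigns flow-cell coordinates (lane 1-8, tile 1-96, pixels
#' uniform on \[0, 30000\]), and with probability `optical_dup_rate` re-emits
#' a record on the same lane and tile with pixel offsets of scale
#' `optical_pixel_sigma` — the optical-duplicate mechanism. True molecule ids
#' are preserved for ground-truth evaluation, so the output can contain
#' slightly more than `n_sequenced` rows when optical duplicates fire.
#'
#' @param pool a `molecule_pool` from [amplify()].
#' @param config a [sim_config()].
#' @return a `hic_pairs` table with `lane`, `tile`, `x`, `y` columns.
#' @export
sequence_library <- function(pool, config) {
  stopifnot(inherits(pool, "molecule_pool"), inherits(config, "sim_config"))
  if (nrow(pool) == 0L) stop("empty molecule pool")
  if (config$n_sequenced < 1) stop("n_sequenced must be >= 1")
  set.seed(stage_seed(config$seed, "sequence"))

  idx <- sample.int(nrow(pool), config$n_sequenced, replace = TRUE,
                    prob = pool$copy_number)
  out <- as.data.frame(pool)[idx, setdiff(names(pool), "copy_number"), drop = FALSE]
  m <- nrow(out)
  out$lane <- sample.int(8L, m, replace = TRUE)
  out$tile <- sample.int(96L, m, replace = TRUE)
  out$x <- round(stats::runif(m, 0, 30000))
  out$y <- round(stats::runif(m, 0, 30000))
  out$read_id <- sprintf("R%08d", seq_len(m))

  dup <- which(stats::runif(m) < config$optical_dup_rate)
  if (length(dup) > 0L) {
    od <- out[dup, , drop = FALSE]
    od$x <- pmin(pmax(od$x + round(stats::rnorm(length(dup), 0, config$optical_pixel_sigma)), 0), 30000)
    od$y <- pmin(pmax(od$y + round(stats::rnorm(length(dup), 0, config$optical_pixel_sigma)), 0), 30000)
    od$read_id <- sprintf("R%08d", m + seq_along(dup))
    out <- rbind(out, od)
  }
  rownames(out) <- NULL
  hic_pairs(out, chrom_order = attr(pool, "chrom_order"),
            chrom_lengths = attr(pool, "chrom_lengths"))
}

#' One-call simulation of a sequenced Hi-C library
#'
#' Convenience wrapper chaining [simulate_genome()],
#' [simulate_true_ligations()], [amplify()] and [sequence_library()].
#'
#' @inheritParams simulate_genome
#' @return list with `genome`, `ligations`, `pool`, `reads`.
#' @export
simulate_library <- function(config, chrom_spec) {
  genome <- simulate_genome(config, chrom_spec)
  lig <- simulate_true_ligations(genome, config)
  pool <- amplify(lig, config)
  reads <- sequence_library(pool, config)
  list(genome = genome, ligations = lig, pool = pool, reads = reads)
}
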