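#' Duplicate-detection parameters
#'
#' @param wobble maximum per-end coordinate difference (bp) for two pairs to
#'   be considered duplicates; 4 bp is the standard deduplication setting.
#' @param optical_pixel_threshold maximum Euclidean pixel distance on a shared
#'   lane/tile for a duplicate to be called optical (HiSeq default 100).
#' @return a `dedup_params` list.
#' @export
dedup_params <- function(wobble = 4, optical_pixel_threshold = 100) {
  if (wobble < 0 || optical_pixel_threshold < 0)
    stop("wobble and optical_pixel_threshold must be >= 0")
  structure(list(wobble = wobble, optical_pixel_threshold = optical_pixel_threshold),
            class = "dedup_params")
}

#' Classify duplicate read pairs as PCR or optical
#'
#' Two records are duplicates iff they share `chrom1, chrom2, strand1,
#' strand2` and both end coordinates differ by at most `wobble` bp; clusters
#' are the single-linkage (transitive) closure of this relation, so the
#' result does not depend on input order. Within each cluster the
#' representative (labelled `unique`) is the record with the
#' lexicographically smallest `(pos1, pos2, read_id)`; every other record is
#' `optical_duplicate` if it shares lane and tile with the representative and
#' lies within `optical_pixel_threshold` pixels of it, else `pcr_duplicate`.
#' Records without flow-cell columns are classified PCR (with a notice),
#' since the optical judgement needs tile/pixel information.
#'
#' @param pairs a [hic_pairs()] table (upper-triangle ordered).
#' @param params a [dedup_params()].
#' @return a `dup_class` data.frame: `read_id`, `label`, `group_id`, `depth`
#'   (cluster size), in input row order.
#' @export
classify_duplicates <- function(pairs, params = dedup_params()) {
  stopifnot(inherits(pairs, "hic_pairs"))
  df <- as.data.frame(pairs)
  n <- nrow(df)
  if (n == 0L) {
    return(structure(data.frame(read_id = character(0), label = character(0),
                                group_id = integer(0), depth = integer(0)),
                     params = params, class = c("dup_class", "data.frame")))
  }
  w <- params$wobble
  has_optics <- all(c("lane", "tile", "x", "y") %in% names(df)) &&
    !anyNA(df$lane) && !anyNA(df$tile) && !anyNA(df$x) && !anyNA(df$y)
  if (!has_optics)
    message("flow-cell columns missing or incomplete: all non-representative duplicates classified as PCR")

  key <- paste(df$chrom1, df$chrom2, df$strand1, df$strand2, sep = "\r")
  parent <- seq_len(n)
  # union-find with path halving; <<- resolves to this function's `parent`
  uf_find <- function(v) {
    while (parent[v] != v) {
      parent[v] <<- parent[parent[v]]
      v <- parent[v]
    }
    v
  }
  groups <- split(seq_len(n), key)
  for (g in groups) {
    m <- length(g)
    if (m < 2L) next
    if (w == 0) {
      sub <- split(g, paste(df$pos1[g], df$pos2[g]))
      for (s in sub) if (length(s) > 1L) {
        r <- uf_find(s[1])
        for (v in s[-1]) parent[uf_find(v)] <- r
      }
    } else {
      o <- g[order(df$pos1[g], df$pos2[g])]
      p1 <- df$pos1[o]; p2 <- df$pos2[o]
      for (a in seq_len(m - 1L)) {
        b <- a + 1L
        while (b <= m && p1[b] - p1[a] <= w) {
          if (abs(p2[b] - p2[a]) <= w) {
            ra <- uf_find(o[a]); rb <- uf_find(o[b])
            if (ra != rb) parent[rb] <- ra
          }
          b <- b + 1L
        }
      }
    }
  }
  root <- vapply(seq_len(n), function(v) uf_find(v), 0L)
  group_id <- match(root, unique(root))
  depth <- tabulate(group_id)[group_id]

  # representative: lexicographically smallest (pos1, pos2, read_id)
  o <- order(group_id, df$pos1, df$pos2, df$read_id)
  rep_row <- o[!duplicated(group_id[o])]           # first row of each cluster
  reps <- integer(max(group_id))
  reps[group_id[rep_row]] <- rep_row
  rep_of <- reps[group_id]

  label <- rep("unique", n)
  dupes <- which(seq_len(n) != rep_of)
  if (length(dupes)) {
    if (has_optics) {
      r <- rep_of[dupes]
      same_tile <- df$lane[dupes] == df$lane[r] & df$tile[dupes] == df$tile[r]
      pix <- sqrt((df$x[dupes] - df$x[r])^2 + (df$y[dupes] - df$y[r])^2)
      optical <- same_tile & pix <= params$optical_pixel_threshold
      label[dupes] <- ifelse(optical, "optical_duplicate", "pcr_duplicate")
    } else {
      label[dupes] <- "pcr_duplicate"
    }
  }
  structure(data.frame(read_id = df$read_id, label = label,
                       group_id = group_id, depth = depth,
                       stringsAsFactors = FALSE),
            params = params, class = c("dup_class", "data.frame"))
}

#' Duplication-depth histogram
#'
#' Fraction of duplicate clusters observed at each depth (copies per ligate).
#' By convention the histogram is over duplicated ligates only (depth >= 2),
#' so the fractions sum to 1 over those clusters; set
#' `include_singletons = TRUE` to include depth-1 clusters.
#'
#' @param dup a `dup_class` from [classify_duplicates()].
#' @param include_singletons include depth-1 clusters in the denominator.
#' @return data.frame `depth`, `n_clusters`, `fraction`.
#' @export
duplication_depth_histogram <- function(dup, include_singletons = FALSE) {
  stopifnot(inherits(dup, "dup_class"))
  if (nrow(dup) == 0L)
    return(data.frame(depth = integer(0), n_clusters = integer(0), fraction = numeric(0)))
  depth_by_cluster <- dup$depth[!duplicated(dup$group_id)]
  if (!include_singletons) depth_by_cluster <- depth_by_cluster[depth_by_cluster >= 2L]
  if (length(depth_by_cluster) == 0L)
    return(data.frame(depth = integer(0), n_clusters = integer(0), fraction = numeric(0)))
  tab <- table(depth_by_cluster)
  data.frame(depth = as.integer(names(tab)),
             n_clusters = as.integer(tab),
             fraction = as.numeric(tab) / sum(tab))
}

#' Summary duplicate statistics
#'
#' Percentages of unique pairs, PCR duplicates, and optical duplicates among
#' the total sequenced pairs; optical duplicates are reported separately
#' because they are excluded from all downstream analysis regardless of
#' library type.
#'
#' @param dup a `dup_class`.
#' @param n_total_sequenced denominator; defaults to `nrow(dup)`.
#' @return list of counts and percentages.
#' @export
dedup_statistics <- function(dup, n_total_sequenced = nrow(dup)) {
  stopifnot(inherits(dup, "dup_class"))
  n_unique <- sum(dup$label == "unique")
  n_pcr <- sum(dup$label == "pcr_duplicate")
  n_opt <- sum(dup$label == "optical_duplicate")
  list(n_total = n_total_sequenced, n_unique = n_unique,
       n_pcr_dup = n_pcr, n_optical_dup = n_opt,
       pct_unique = 100 * n_unique / n_total_sequenced,
       pct_pcr_dup = 100 * n_pcr / n_total_sequenced,
       pct_optical_dup = 100 * n_opt / n_total_sequenced)
}

#' Retain the valid read pairs of a library
#'
#' Amplified libraries keep one representative per duplicate cluster. In
#' SAFE mode (an amplification-free library) duplicates are independent
#' ligation events and are kept; only optical duplicates are removed.
#'
#' @param pairs a [hic_pairs()] table.
#' @param dup matching `dup_class` (computed if missing).
#' @param safe_mode the library was prepared without amplification.
#' @param params passed to [classify_duplicates()] when `dup` is missing.
#' @return filtered `hic_pairs`.
#' @export
apply_dedup <- function(pairs, dup = NULL, safe_mode = FALSE, params = dedup_params()) {
  if (is.null(dup)) dup <- classify_duplicates(pairs, params)
  stopifnot(nrow(dup) == nrow(pairs))
  keep <- if (safe_mode) dup$label != "optical_duplicate" else dup$label == "unique"
  out <- as.data.frame(pairs)[keep, , drop = FALSE]
  hic_pairs(out, chrom_order = attr(pairs, "chrom_order"),
            chrom_lengths = attr(pairs, "chrom_lengths"))
}

#' Sequencing-saturation curve
#'
#' For each depth fraction `f`, subsamples `floor(f * n)` records without
#' replacement, re-runs duplicate classification, and reports the fraction of
#' unique pairs — the accumulated unique yield against sequencing depth.
#' Fractions of zero (empty subsample) are omitted.
#'
#' @param pairs a [hic_pairs()] table.
#' @param fractions depth fractions in (0, 1].
#' @param seed RNG seed for the subsampling.
#' @param params a [dedup_params()].
#' @return data.frame `depth_fraction`, `n_subsampled`, `unique_fraction`.
#' @export
saturation_curve <- function(pairs, fractions = seq(0.1, 1, by = 0.1),
                             seed = 1L, params = dedup_params()) {
  stopifnot(inherits(pairs, "hic_pairs"))
  n <- nrow(pairs)
  fractions <- fractions[fractions > 0 & fractions <= 1]
  set.seed(as.integer(seed))
  rows <- lapply(fractions, function(f) {
    k <- floor(f * n)
    if (k == 0L) return(NULL)
    idx <- sort(sample.int(n, k))
    sub <- hic_pairs(as.data.frame(pairs)[idx, , drop = FALSE],
                     chrom_order = attr(pairs, "chrom_order"),
                     chrom_lengths = attr(pairs, "chrom_lengths"))
    dup <- classify_duplicates(sub, params)
    data.frame(depth_fraction = f, n_subsampled = k,
               unique_fraction = sum(dup$label == "unique") / k)
  })
  do.call(rbind, rows)
}
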