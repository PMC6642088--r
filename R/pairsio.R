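#' Construct a validated table of Hi-C read pairs
#'
#' Canonical in-memory form of aligned ligation products. Required columns:
#' `read_id`, `chrom1`, `pos1`, `strand1`, `chrom2`, `pos2`, `strand2`;
#' optional: `lane`, `tile`, `x`, `y` (flow-cell coordinates), `gc`
#' (fragment-pair GC fraction), `mid` (true molecule id, simulations only).
#' Records are flipped into upper-triangle order — `(chrom1, pos1) <=
#' (chrom2, pos2)` under the fixed chromosome order — positions are 1-based.
#'
#' @param df data.frame of records.
#' @param chrom_order chromosome ordering; defaults to order of first
#'   appearance.
#' @param chrom_lengths optional named lengths, carried as an attribute.
#' @return a `hic_pairs` data.frame.
#' @export
hic_pairs <- function(df, chrom_order = NULL, chrom_lengths = NULL) {
  req <- c("chrom1", "pos1", "chrom2", "pos2")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!"read_id" %in% names(df)) df$read_id <- sprintf("P%08d", seq_len(nrow(df)))
  if (!"strand1" %in% names(df)) df$strand1 <- "+"
  if (!"strand2" %in% names(df)) df$strand2 <- "+"
  if (nrow(df) > 0L) {
    if (any(!is.finite(df$pos1)) || any(!is.finite(df$pos2)) ||
        any(df$pos1 < 1) || any(df$pos2 < 1))
      stop("positions must be finite and >= 1")
    if (!all(c(df$strand1, df$strand2) %in% c("+", "-")))
      stop("strands must be '+' or '-'")
  }
  if (is.null(chrom_order)) chrom_order <- unique(c(df$chrom1, df$chrom2))
  unknown <- setdiff(unique(c(df$chrom1, df$chrom2)), chrom_order)
  if (length(unknown)) stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))

  ci1 <- match(df$chrom1, chrom_order)
  ci2 <- match(df$chrom2, chrom_order)
  flip <- ci2 < ci1 | (ci1 == ci2 & df$pos2 < df$pos1)
  if (any(flip)) {
    swap <- function(a, b) { tmp <- df[[a]][flip]; df[[a]][flip] <<- df[[b]][flip]; df[[b]][flip] <<- tmp }
    swap("chrom1", "chrom2"); swap("pos1", "pos2"); swap("strand1", "strand2")
  }
  lead <- intersect(c("read_id", "chrom1", "pos1", "chrom2", "pos2",
                      "strand1", "strand2", "lane", "tile", "x", "y", "gc", "mid"),
                    names(df))
  df <- df[, c(lead, setdiff(names(df), lead)), drop = FALSE]
  rownames(df) <- NULL
  attr(df, "chrom_order") <- chrom_order
  attr(df, "chrom_lengths") <- chrom_lengths
  class(df) <- c("hic_pairs", "data.frame")
  df
}

PAIRS_CORE <- c("readID", "chrom1", "pos1", "chrom2", "pos2", "strand1", "strand2")
PAIRS_EXT <- c("lane", "tile", "x", "y", "gc", "mid")
pairs_col_map <- c(readID = "read_id", chrom1 = "chrom1", pos1 = "pos1",
                   chrom2 = "chrom2", pos2 = "pos2", strand1 = "strand1",
                   strand2 = "strand2", lane = "lane", tile = "tile",
                   x = "x", y = "y", gc = "gc", mid = "mid")

#' Write read pairs as 4DN-style `.pairs` text
#'
#' Header carries `#chromsize:` lines (defining the chromosome order as order
#' of appearance) and a `#columns:` line; optional columns `lane tile x y gc
#' mid` follow the seven core columns. Output rows are sorted by (chrom1,
#' pos1, chrom2, pos2, read id) so writing is deterministic.
#'
#' @param pairs a [hic_pairs()] table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  stopifnot(inherits(pairs, "hic_pairs"))
  chrom_order <- attr(pairs, "chrom_order")
  lens <- attr(pairs, "chrom_lengths")
  ext <- intersect(PAIRS_EXT, names(pairs))
  cols <- c(PAIRS_CORE, ext)
  hdr <- c("## pairs format v1.0",
           sprintf("#chromsize: %s %s", chrom_order,
                   if (is.null(lens)) 0 else as.integer(lens[chrom_order])),
           paste("#columns:", paste(cols, collapse = " ")))
  df <- as.data.frame(pairs)
  o <- order(match(df$chrom1, chrom_order), df$pos1,
             match(df$chrom2, chrom_order), df$pos2, df$read_id)
  df <- df[o, pairs_col_map[cols], drop = FALSE]
  writeLines(hdr, path)
  if (nrow(df) > 0L)
    data.table::fwrite(df, path, sep = "\t", append = TRUE, col.names = FALSE)
  invisible(path)
}

#' Read a 4DN-style `.pairs` file
#'
#' @param path input file (plain text or gzipped).
#' @return a [hic_pairs()] table; chromosome order and lengths are taken from
#'   the `#chromsize:` header lines.
#' @export
read_pairs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr <- lines[is_hdr]
  body <- lines[!is_hdr]
  cs <- hdr[startsWith(hdr, "#chromsize:")]
  if (length(cs) == 0L) stop("missing #chromsize: header")
  cs_parts <- strsplit(trimws(sub("^#chromsize:", "", cs)), "\\s+")
  chrom_order <- vapply(cs_parts, `[[`, "", 1L)
  lens <- as.numeric(vapply(cs_parts, `[[`, "", 2L))
  names(lens) <- chrom_order
  colline <- hdr[startsWith(hdr, "#columns:")]
  if (length(colline) != 1L) stop("missing #columns: header")
  cols <- strsplit(trimws(sub("^#columns:", "", colline)), "\\s+")[[1]]
  unknown_cols <- setdiff(cols, names(pairs_col_map))
  if (length(unknown_cols)) stop("unknown columns: ", paste(unknown_cols, collapse = ", "))

  if (length(body) == 0L) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), pairs_col_map[cols]))
    df$pos1 <- numeric(0); df$pos2 <- numeric(0)
    return(hic_pairs(df, chrom_order = chrom_order, chrom_lengths = lens))
  }
  nf <- lengths(strsplit(body, "\t", fixed = TRUE))
  bad <- which(nf != length(cols))
  if (length(bad)) {
    lineno <- which(!is_hdr)[bad[1]]
    stop(sprintf("malformed line %d: expected %d fields, found %d",
                 lineno, length(cols), nf[bad[1]]))
  }
  dt <- data.table::fread(text = body, sep = "\t", header = FALSE,
                          col.names = pairs_col_map[cols], data.table = FALSE)
  for (col in c("pos1", "pos2"))
    if (any(is.na(dt[[col]]))) stop("non-numeric position in ", col)
  hic_pairs(dt, chrom_order = chrom_order, chrom_lengths = lens)
}

#' Construct a per-chromosome sparse contact matrix
#'
#' Upper-triangle COO storage (`0 <= i <= j < n_bins`, 0-based bins, bin index
#' `floor((pos - 1) / resolution)`), with optional balancing weights.
#'
#' @param chrom chromosome name.
#' @param resolution bin size, bp.
#' @param n_bins number of bins.
#' @param i,j 0-based bin indices, `i <= j`.
#' @param x counts (or balanced values).
#' @param weights optional per-bin balancing weights (NA = masked bin).
#' @param balanced logical flag.
#' @return a `contact_matrix` object.
#' @export
contact_matrix <- function(chrom, resolution, n_bins, i, j, x,
                           weights = NULL, balanced = FALSE) {
  i <- as.integer(i); j <- as.integer(j)
  if (length(i) != length(j) || length(i) != length(x))
    stop("i, j, x must have equal length")
  if (any(is.na(x)) || any(x < 0)) stop("matrix entries must be non-negative and non-missing")
  if (any(i < 0L) || any(j >= n_bins) || any(i > j))
    stop("need 0 <= i <= j < n_bins")
  o <- order(i, j)
  m <- list(chrom = chrom, resolution = resolution, n_bins = as.integer(n_bins),
            i = i[o], j = j[o], x = x[o],
            weights = weights, balanced = isTRUE(balanced))
  class(m) <- "contact_matrix"
  m
}

#' Dense symmetric completion of a contact matrix
#'
#' @param m a [contact_matrix()].
#' @param balanced if `TRUE`, apply balancing weights (`w_i w_j x_ij`);
#'   masked bins become `NA` rows/columns.
#' @return an `n_bins` x `n_bins` base matrix.
#' @export
as_dense <- function(m, balanced = FALSE) {
  stopifnot(inherits(m, "contact_matrix"))
  n <- m$n_bins
  D <- matrix(0, n, n)
  D[cbind(m$i + 1L, m$j + 1L)] <- m$x
  D[cbind(m$j + 1L, m$i + 1L)] <- m$x
  if (balanced) {
    if (is.null(m$weights)) stop("matrix has no balancing weights; run kr_balance() first")
    w <- m$weights
    D <- D * tcrossprod(w)       # NA weights propagate to masked rows/cols
  }
  D
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s @ %d bp: %d bins, %d non-zero, %s\n",
              x$chrom, as.integer(x$resolution), x$n_bins, length(x$x),
              if (!is.null(x$weights)) "balanced weights present" else "raw"))
  invisible(x)
}

#' Write / read a contact matrix as COO text
#'
#' Header line `#contact_matrix chrom= resolution= n_bins=`, an optional
#' `#weights:` line, then sorted `i j value` triplets (0-based, upper
#' triangle).
#'
#' @param m a [contact_matrix()].
#' @param path file path.
#' @return `path` invisibly / the matrix.
#' @export
write_matrix <- function(m, path) {
  stopifnot(inherits(m, "contact_matrix"))
  hdr <- sprintf("#contact_matrix chrom=%s resolution=%d n_bins=%d balanced=%s",
                 m$chrom, as.integer(m$resolution), m$n_bins, m$balanced)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (!is.null(m$weights))
    writeLines(paste("#weights:", paste(format(m$weights, digits = 17, trim = TRUE),
                                        collapse = " ")), con)
  writeLines(paste(m$i, m$j, format(m$x, digits = 17, trim = TRUE)), con)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- lines[1]
  if (!startsWith(hdr, "#contact_matrix")) stop("not a contact-matrix file")
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1]]
  fields <- setNames(sub("^[a-z_]+=", "", kv), sub("=.*$", "", kv))
  weights <- NULL
  body_start <- 2L
  if (length(lines) >= 2L && startsWith(lines[2], "#weights:")) {
    weights <- as.numeric(strsplit(trimws(sub("^#weights:", "", lines[2])), "\\s+")[[1]])
    body_start <- 3L
  }
  body <- lines[seq.int(body_start, length(lines))]
  body <- body[nzchar(body)]
  if (length(body)) {
    dt <- data.table::fread(text = body, sep = " ", header = FALSE,
                            col.names = c("i", "j", "x"), data.table = FALSE)
    if (any(is.na(dt$x)) || any(dt$x < 0)) stop("matrix entries must be non-negative numbers")
  } else {
    dt <- data.frame(i = integer(0), j = integer(0), x = numeric(0))
  }
  contact_matrix(fields[["chrom"]], as.numeric(fields[["resolution"]]),
                 as.integer(fields[["n_bins"]]), dt$i, dt$j, dt$x,
                 weights = weights, balanced = identical(fields[["balanced"]], "TRUE"))
}

#' Read / write BED intervals (0-based, half-open)
#'
#' @param x data.frame with `chrom`, `start`, `end` (bp).
#' @param path file path.
#' @return the interval data.frame / `path` invisibly.
#' @export
write_bed <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) > 1L) {
    o <- order(x$chrom, x$start, x$end)
    x <- x[o, , drop = FALSE]
    same <- x$chrom[-1] == x$chrom[-nrow(x)]
    if (any(same & x$start[-1] < x$end[-nrow(x)]))
      warning("overlapping intervals written to ", path)
  }
  data.table::fwrite(x[, c("chrom", "start", "end")], path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (length(readLines(path, n = 1L)) == 0L)
    return(data.frame(chrom = character(0), start = numeric(0), end = numeric(0)))
  dt <- data.table::fread(path, sep = "\t", header = FALSE, data.table = FALSE)
  names(dt)[1:3] <- c("chrom", "start", "end")
  if (any(dt$end <= dt$start)) stop("BED intervals must satisfy end > start")
  dt[, 1:3]
}

#' Read / write BEDPE anchor pairs
#'
#' @param x data.frame with `chrom1,start1,end1,chrom2,start2,end2`.
#' @param path file path.
#' @return the data.frame / `path` invisibly.
#' @export
write_bedpe <- function(x, path) {
  cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  stopifnot(all(cols %in% names(x)))
  o <- order(x$chrom1, x$start1, x$chrom2, x$start2)
  data.table::fwrite(x[o, cols], path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_bedpe
#' @export
read_bedpe <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  if (length(readLines(path, n = 1L)) == 0L)
    return(as.data.frame(setNames(rep(list(numeric(0)), 6), cols)))
  dt <- data.table::fread(path, sep = "\t", header = FALSE, data.table = FALSE)
  names(dt)[1:6] <- cols
  dt[, 1:6]
}

#' Loop anchors from a genome model as BEDPE midpoint intervals
#' @param genome a `genome_model`.
#' @param half half-width of the anchor interval, bp.
#' @return BEDPE data.frame.
#' @export
loops_to_bedpe <- function(genome, half = 5000) {
  lp <- genome$loops
  data.frame(chrom1 = lp$chrom, start1 = pmax(lp$anchor1 - half, 0), end1 = lp$anchor1 + half,
             chrom2 = lp$chrom, start2 = pmax(lp$anchor2 - half, 0), end2 = lp$anchor2 + half)
}
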