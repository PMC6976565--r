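#' Default feline karyotype layout
#'
#' The 19 chromosomes of the domestic cat (*Felis catus*): autosome groups
#' A1--A3, B1--B4, C1--C2, D1--D4, E1--E3, F1--F2 plus X. Lengths are
#' reference-assembly chromosome sizes rounded to whole megabases; they can be
#' overridden by [read_layout()] with a two-column TSV, since assembly builds
#' differ slightly.
#'
#' @return A `genome_layout` object: data.frame with columns `chrom`, `length`.
#' @export
feline_layout <- function() {
  chrom <- c("A1", "A2", "A3", "B1", "B2", "B3", "B4", "C1", "C2",
             "D1", "D2", "D3", "D4", "E1", "E2", "E3", "F1", "F2", "X")
  length_mb <- c(240, 171, 143, 208, 155, 149, 144, 222, 161,
                 117, 90, 96, 96, 63, 64, 43, 71, 85, 131)
  genome_layout(chrom, length_mb * 1e6)
}

#' Construct a genome layout
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Numeric vector of chromosome lengths in base pairs (> 0).
#' @return A `genome_layout` data.frame with columns `chrom`, `length`.
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) != length(length)) stop("chrom and length differ in length")
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(!is.finite(length)) || any(length <= 0)) stop("chromosome lengths must be positive")
  structure(data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE),
            class = c("genome_layout", "data.frame"))
}

#' Read a genome layout from a two-column TSV (name, length)
#'
#' @param path Path to a headerless TSV with chromosome name and length (bp).
#' @return A `genome_layout`.
#' @export
read_layout <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  genome_layout(df$chrom, df$length)
}

chrom_length <- function(layout, chrom) {
  i <- match(chrom, layout$chrom)
  if (anyNA(i)) stop("unknown chromosome(s): ", paste(chrom[is.na(i)], collapse = ", "))
  layout$length[i]
}

#' Build a window grid over a genome layout
#'
#' Fixed mode tiles each chromosome with non-overlapping windows of
#' `window_size`; sliding mode places `window_size`-wide windows every
#' `window_size / 2` bases (so interior windows overlap their neighbours by
#' half a window). Terminal windows shorter than `window_size` are retained
#' only if at least half a window long; in fixed mode a shorter tail is merged
#' into the previous window, in sliding mode it is already covered by the
#' previous (truncated) window and dropped.
#'
#' @param layout A `genome_layout`.
#' @param window_size Window width in base pairs (default 2 Mb).
#' @param mode `"fixed"` or `"sliding"`.
#' @return A `window_grid`: data.frame with columns `chrom`, `start`, `stop`
#'   (0-based half-open bp), plus attributes `layout`, `window_size`, `mode`.
#' @export
build_grid <- function(layout, window_size = 2e6, mode = c("fixed", "sliding")) {
  mode <- match.arg(mode)
  stopifnot(inherits(layout, "genome_layout"))
  if (!is.numeric(window_size) || length(window_size) != 1 || window_size <= 0)
    stop("window_size must be a positive scalar")
  if (window_size > max(layout$length))
    stop("window_size exceeds the longest chromosome")
  rows <- lapply(seq_len(nrow(layout)), function(i) {
    len <- layout$length[i]
    if (mode == "fixed") {
      starts <- seq(0, len - 1, by = window_size)
      stops <- pmin(starts + window_size, len)
      n <- length(starts)
      if (n > 1 && (stops[n] - starts[n]) < window_size / 2) {
        # short tail: merge into previous window
        stops[n - 1] <- stops[n]
        starts <- starts[-n]; stops <- stops[-n]
      }
    } else {
      step <- window_size / 2
      starts <- seq(0, len - 1, by = step)
      stops <- pmin(starts + window_size, len)
      keep <- (stops - starts) >= step
      # a truncated window whose stop does not extend past the previous kept
      # window adds no new territory
      keep <- keep & c(TRUE, diff(stops) > 0)
      starts <- starts[keep]; stops <- stops[keep]
    }
    data.frame(chrom = layout$chrom[i], start = starts, stop = stops,
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, rows)
  rownames(grid) <- NULL
  structure(grid, layout = layout, window_size = window_size, mode = mode,
            class = c("window_grid", "data.frame"))
}

#' Construct genomic regions
#'
#' Coordinates are 0-based half-open internally; [format_region()] renders the
#' 1-based inclusive Mb style used in reports.
#'
#' @param chrom,start,stop Vectors defining the intervals (bp, half-open).
#' @param sign `"gain"`, `"loss"` or `"neutral"` per region.
#' @param layout Optional `genome_layout` to validate against.
#' @return data.frame with columns `chrom`, `start`, `stop`, `sign`.
#' @export
genomic_region <- function(chrom, start, stop, sign = "neutral", layout = NULL) {
  n <- max(length(chrom), length(start), length(stop), length(sign))
  df <- data.frame(chrom = as.character(rep_len(chrom, n)),
                   start = as.numeric(rep_len(start, n)),
                   stop = as.numeric(rep_len(stop, n)),
                   sign = as.character(rep_len(sign, n)),
                   stringsAsFactors = FALSE)
  if (any(df$start >= df$stop)) stop("regions must satisfy start < stop")
  if (!all(df$sign %in% c("gain", "loss", "neutral"))) stop("invalid sign")
  if (!is.null(layout) && !all(df$chrom %in% layout$chrom))
    stop("region chromosome not in layout")
  df
}

#' Render a region in 1-based inclusive Mb notation (e.g. "B1 1-23 Mb")
#' @param region A region data.frame row set from [genomic_region()].
#' @return Character vector.
#' @export
format_region <- function(region) {
  sprintf("%s %g-%g Mb", region$chrom, region$start / 1e6 + 1, region$stop / 1e6)
}

#' Fraction of a query region covered by same-sign regions
#'
#' One-directional overlap: the number of bases of `a` covered by the union of
#' regions in `b_set` on the same chromosome with the same sign, divided by the
#' length of `a`. An empty `b_set` gives 0.
#'
#' @param a A single-row region (list or one-row data.frame with `chrom`,
#'   `start`, `stop`, `sign`).
#' @param b_set A region data.frame (0 or more rows).
#' @return Fraction in \[0, 1\].
#' @export
overlap_fraction <- function(a, b_set) {
  a <- as.list(a)
  if (is.null(b_set) || nrow(b_set) == 0) return(0)
  b <- b_set[b_set$chrom == a$chrom & b_set$sign == a$sign, , drop = FALSE]
  if (nrow(b) == 0) return(0)
  covered_bases(a$start, a$stop, b$start, b$stop) / (a$stop - a$start)
}

# bases of [qs, qe) covered by the union of [s_i, e_i)
covered_bases <- function(qs, qe, s, e) {
  s <- pmax(s, qs); e <- pmin(e, qe)
  keep <- s < e
  s <- s[keep]; e <- e[keep]
  if (length(s) == 0) return(0)
  o <- order(s)
  s <- s[o]; e <- e[o]
  tot <- 0; cur_s <- s[1]; cur_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] > cur_e) { tot <- tot + (cur_e - cur_s); cur_s <- s[i]; cur_e <- e[i] }
    else cur_e <- max(cur_e, e[i])
  }
  tot + (cur_e - cur_s)
}

#' Map a region to the grid windows whose midpoints it contains
#'
#' A window belongs to the region iff its midpoint lies inside the half-open
#' interval `[start, stop)`.
#'
#' @param region Single region (list or one-row data.frame).
#' @param grid A `window_grid`.
#' @return Integer vector of row indices into `grid` (possibly empty).
#' @export
region_to_windows <- function(region, grid) {
  region <- as.list(region)
  if (!region$chrom %in% grid$chrom) stop("region chromosome not on grid layout")
  mid <- (grid$start + grid$stop) / 2
  which(grid$chrom == region$chrom & mid >= region$start & mid < region$stop)
}

#' Read BED3+ regions (column 4 = "gain"/"loss", optional)
#' @param path BED-like TSV path.
#' @param layout Optional layout to validate against.
#' @return Region data.frame (plus `sample_id` column if a 5th column exists).
#' @export
read_regions_bed <- function(path, layout = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("malformed BED: need at least 3 columns")
  out <- genomic_region(df[[1]], df[[2]], df[[3]],
                        sign = if (ncol(df) >= 4) df[[4]] else "neutral",
                        layout = layout)
  if (ncol(df) >= 5) out$sample_id <- as.character(df[[5]])
  out
}

#' Write regions (or a grid) as BED
#' @param regions data.frame with `chrom`, `start`, `stop` and optionally
#'   `sign`, `sample_id`.
#' @param path Output path.
#' @export
write_regions_bed <- function(regions, path) {
  cols <- c("chrom", "start", "stop",
            intersect(c("sign", "sample_id"), names(regions)))
  utils::write.table(regions[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
}
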