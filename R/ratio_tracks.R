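#' Compute a windowed log2 copy-number ratio track
#'
#' Library-size-normalized depth ratio per window:
#' `log2( (tumor/sum(tumor)) / (normal/sum(normal)) )`. The normalization makes
#' the track invariant to global scaling of either count vector. Windows with
#' zero normal counts are masked (NA) rather than mapped to +/-Inf; masked
#' windows are excluded from segmentation downstream. Caller style `"A_sliding"`
#' corresponds to a CNV-seq-like sliding grid, `"B_fixed"` to a CNVKit-like
#' fixed grid (which is the style that receives mode centring).
#'
#' @param tumor_counts,normal_counts Non-negative counts aligned to `grid`.
#' @param grid The `window_grid` the counts live on.
#' @param caller `"A_sliding"` or `"B_fixed"`.
#' @param sample_id Optional sample label.
#' @return A `ratio_track`: data.frame with columns `chrom`, `start`, `stop`,
#'   `log2`; attributes `grid`, `caller`, `sample_id`.
#' @export
compute_log2_track <- function(tumor_counts, normal_counts, grid,
                               caller = c("A_sliding", "B_fixed"),
                               sample_id = NA_character_) {
  caller <- match.arg(caller)
  if (length(tumor_counts) != nrow(grid) || length(normal_counts) != nrow(grid))
    stop("counts must match the grid length")
  if (all(normal_counts == 0)) stop("all-zero normal track")
  t_rel <- tumor_counts / sum(tumor_counts)
  n_rel <- normal_counts / sum(normal_counts)
  v <- ifelse(normal_counts > 0 & tumor_counts > 0, log2(t_rel / n_rel), NA_real_)
  # tumor zero with normal coverage is a real (deep-loss) signal floor, but at
  # log2 it is -Inf; mask it the same way as normal dropout
  structure(data.frame(chrom = grid$chrom, start = grid$start,
                       stop = grid$stop, log2 = v, stringsAsFactors = FALSE),
            grid = grid, caller = caller, sample_id = sample_id,
            class = c("ratio_track", "data.frame"))
}

#' Mode-centre a log2 track
#'
#' Aneuploid tumours can shift the copy-neutral level away from zero; mode
#' centring subtracts the modal log2 value so the dominant (presumed neutral)
#' state sits at zero. The mode is estimated from a fixed-width histogram
#' (deterministic, unlike a KDE): values are assigned to bins of width
#' `bin_width` centred on multiples of `bin_width`; the most populated bin
#' wins, ties broken toward the bin nearest zero (then toward the lower bin).
#' On noisy tracks a single 0.05 bin holds too few windows for its count to
#' identify the mode, so with `smooth = "auto"` (the default) bin counts are
#' first smoothed with a centred moving sum whose half-width matches the
#' robust per-window noise SD; for low-noise or degenerate tracks this
#' reduces to the raw histogram.
#'
#' @param track A `ratio_track` (caller-B style).
#' @param bin_width Histogram bin width (default 0.05 log2 units).
#' @param smooth `"auto"` (noise-matched moving sum), `"none"`, or an integer
#'   half-width in bins.
#' @return The shifted `ratio_track`, with attribute `centre_shift`.
#' @export
centre_mode <- function(track, bin_width = 0.05, smooth = "auto") {
  stopifnot(inherits(track, "ratio_track"))
  v <- track$log2[is.finite(track$log2)]
  if (length(v) < 20) stop("fewer than 20 unmasked windows; mode unstable")
  bin <- round(v / bin_width)
  rng <- range(bin)
  counts <- tabulate(bin - rng[1] + 1L, nbins = rng[2] - rng[1] + 1L)
  centres <- (rng[1]:rng[2]) * bin_width
  k <- if (identical(smooth, "none")) 0L
  else if (identical(smooth, "auto")) {
    s <- estimate_noise_sd(v)
    if (is.finite(s)) as.integer(min(round(s / bin_width), length(counts) %/% 2)) else 0L
  } else as.integer(smooth)
  if (k > 0) {
    padded <- c(rep(0, k), counts, rep(0, k))
    counts <- vapply(seq_along(centres),
                     function(i) sum(padded[i:(i + 2 * k)]), numeric(1))
  }
  best <- which(counts == max(counts))
  if (length(best) > 1) {
    cand <- centres[best]
    best <- best[order(abs(cand), cand)][1]
  }
  shift <- centres[best]
  out <- track
  out$log2 <- track$log2 - shift
  attr(out, "centre_shift") <- shift
  out
}

#' Read / write ratio tracks as BED4-style TSV (chrom, start, stop, log2)
#' @param track A `ratio_track`.
#' @param path File path.
#' @export
write_track <- function(track, path) {
  utils::write.table(as.data.frame(track)[, c("chrom", "start", "stop", "log2")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
}

#' @rdname write_track
#' @param grid Grid the stored track lives on.
#' @param caller,sample_id Track metadata (see [compute_log2_track()]).
#' @export
read_track <- function(path, grid, caller = "B_fixed", sample_id = NA_character_) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "stop", "log2"))
  if (nrow(df) != nrow(grid)) stop("stored track does not match grid")
  structure(data.frame(chrom = grid$chrom, start = grid$start,
                       stop = grid$stop, log2 = df$log2),
            grid = grid, caller = caller, sample_id = sample_id,
            class = c("ratio_track", "data.frame"))
}
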