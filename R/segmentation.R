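#' Segmentation parameters
#'
#' @param gamma Penalty per breakpoint (on the noise-standardized scale when
#'   `scale_penalty = TRUE` in [segment_track()]); must be >= 0.
#' @param kmin Minimum number of windows per segment (>= 1).
#' @return A `seg_params` list.
#' @export
seg_params <- function(gamma, kmin) {
  stopifnot(is.numeric(gamma), length(gamma) == 1, gamma >= 0,
            is.numeric(kmin), length(kmin) == 1, kmin >= 1)
  structure(list(gamma = gamma, kmin = as.integer(kmin)), class = "seg_params")
}

#' Penalized piecewise-constant objective
#'
#' The cost the segmentation minimizes: total within-segment squared deviation
#' from segment means plus `gamma` per breakpoint.
#'
#' @param values Numeric vector (no NA).
#' @param breakpoints Integer vector of segment start positions excluding the
#'   first (i.e. a breakpoint `b` means a new segment starts at index `b`);
#'   empty for a single segment.
#' @param gamma Penalty per breakpoint.
#' @param kmin If supplied, validate that every segment has >= kmin points.
#' @return The scalar cost.
#' @export
pl_objective <- function(values, breakpoints, gamma, kmin = NULL) {
  n <- length(values)
  bp <- sort(unique(as.integer(breakpoints)))
  if (any(bp < 2 | bp > n)) stop("breakpoints out of range")
  starts <- c(1L, bp)
  stops <- c(bp - 1L, n)
  if (!is.null(kmin) && any(stops - starts + 1L < kmin))
    stop("segment shorter than kmin")
  sse <- 0
  for (k in seq_along(starts)) {
    seg <- values[starts[k]:stops[k]]
    sse <- sse + sum((seg - mean(seg))^2)
  }
  sse + gamma * length(bp)
}

# robust per-window noise SD from lag-1 differences (insensitive to true
# copy-number level shifts, which affect only a handful of differences)
estimate_noise_sd <- function(values) {
  d <- diff(values)
  d <- d[is.finite(d)]
  if (length(d) < 2) return(NA_real_)
  stats::mad(d) / sqrt(2)
}

#' Segment a log2 ratio track into piecewise-constant segments
#'
#' Exact global minimizer (dynamic programming, per chromosome) of
#' \deqn{\sum_{segments} SSE + \gamma_{eff} (\#segments - 1)}
#' subject to every segment spanning at least `kmin` unmasked windows.
#' With `scale_penalty = TRUE` (default) the effective penalty is
#' `gamma * sigma^2` where `sigma` is a robust per-window noise SD estimated
#' from lag-1 differences, so `gamma` is expressed on the noise-standardized
#' scale used by the penalized least-squares segmentation literature; this is
#' what makes values like gamma = 10 or 20 meaningful for log2 data.
#'
#' Masked (NA) windows are removed before segmentation and segment boundaries
#' are mapped back through the unmasked index. Chromosomes with fewer than
#' `kmin` unmasked windows become a single segment with a warning.
#'
#' @param track A `ratio_track` from [compute_log2_track()].
#' @param params A [seg_params()].
#' @param scale_penalty Multiply `gamma` by the estimated noise variance.
#' @return A `segment_set`: data.frame with columns `chrom`, `start`, `stop`
#'   (bp), `start_window`, `stop_window` (row indices into the track grid),
#'   `n_windows`, `mean_log2`; attributes `sample_id`, `caller`,
#'   `objective_value`, `grid`.
#' @export
segment_track <- function(track, params, scale_penalty = TRUE) {
  stopifnot(inherits(track, "ratio_track"), inherits(params, "seg_params"))
  grid <- attr(track, "grid")
  values <- track$log2
  gamma_eff <- params$gamma
  if (scale_penalty) {
    s2 <- estimate_noise_sd(values)^2
    if (is.finite(s2) && s2 > 0) gamma_eff <- params$gamma * s2
  }
  segs <- list()
  total_obj <- 0
  for (ch in unique(grid$chrom)) {
    idx <- which(grid$chrom == ch)
    ok <- idx[is.finite(values[idx])]
    if (length(ok) == 0) next
    x <- values[ok]
    if (length(x) < params$kmin) {
      warning("chromosome ", ch, " has fewer than kmin unmasked windows; single segment")
      starts_local <- 1L
    } else {
      starts_local <- .dp_segment(x, gamma_eff, params$kmin)
    }
    stops_local <- c(starts_local[-1] - 1L, length(x))
    for (k in seq_along(starts_local)) {
      w <- ok[starts_local[k]:stops_local[k]]
      segs[[length(segs) + 1]] <- data.frame(
        chrom = ch,
        start = grid$start[w[1]],
        stop = grid$stop[w[length(w)]],
        start_window = w[1],
        stop_window = w[length(w)],
        n_windows = length(w),
        mean_log2 = mean(x[starts_local[k]:stops_local[k]]),
        stringsAsFactors = FALSE)
    }
    total_obj <- total_obj +
      pl_objective(x, starts_local[-1], gamma_eff)
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  structure(out,
            sample_id = attr(track, "sample_id"),
            caller = attr(track, "caller"),
            objective_value = total_obj,
            grid = grid,
            class = c("segment_set", "data.frame"))
}

#' Write a segment set as an IGV SEG-like TSV
#' @param segset A `segment_set`.
#' @param path Output path.
#' @export
write_seg <- function(segset, path) {
  df <- data.frame(sample = attr(segset, "sample_id"),
                   chrom = segset$chrom, start = segset$start,
                   stop = segset$stop, n_windows = segset$n_windows,
                   mean_log2 = segset$mean_log2)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Segment a bare numeric vector (single chromosome)
#'
#' The core exact DP without grid bookkeeping, useful for direct comparison
#' against enumeration on small inputs. No penalty scaling is applied:
#' `gamma` is used exactly as given.
#'
#' @param values Numeric vector, no NA.
#' @param gamma Penalty per breakpoint.
#' @param kmin Minimum segment length.
#' @return List: `starts` (segment start indices), `breakpoints`
#'   (`starts[-1]`), `objective` (the achieved cost).
#' @export
segment_values <- function(values, gamma, kmin = 1) {
  stopifnot(is.numeric(values), !anyNA(values), gamma >= 0, kmin >= 1)
  starts <- .dp_segment(values, gamma, as.integer(kmin))
  list(starts = starts, breakpoints = starts[-1],
       objective = pl_objective(values, starts[-1], gamma))
}
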