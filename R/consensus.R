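#' Consensus parameters
#'
#' Caller-specific significance thresholds and the overlap requirement for
#' dual-caller validation. All threshold comparisons are strict inequalities.
#' Defaults: caller A (CNV-seq style) gain > 0.2 / loss < -0.2; caller B
#' (CNVKit style) gain > 0.2 / loss < -0.1; minimum overlap fraction 0.8.
#'
#' @param gain_a,loss_a Caller-A gain/loss thresholds.
#' @param gain_b,loss_b Caller-B gain/loss thresholds.
#' @param overlap_min Minimum fraction of a caller-A region that must be
#'   covered by same-sign caller-B regions, in (0, 1].
#' @return A `consensus_params` list.
#' @export
consensus_params <- function(gain_a = 0.2, loss_a = -0.2,
                             gain_b = 0.2, loss_b = -0.1,
                             overlap_min = 0.8) {
  stopifnot(gain_a > 0, loss_a < 0, gain_b > 0, loss_b < 0,
            overlap_min > 0, overlap_min <= 1)
  structure(list(gain_a = gain_a, loss_a = loss_a, gain_b = gain_b,
                 loss_b = loss_b, overlap_min = overlap_min),
            class = "consensus_params")
}

#' Threshold segments into significant gain/loss regions
#'
#' Segments whose mean log2 exceeds the caller's gain threshold (strictly)
#' become gain regions, those strictly below the loss threshold become loss
#' regions; the rest are dropped. Adjacent significant segments of the same
#' sign (contiguous in the unmasked window index) are merged, with a
#' window-weighted mean.
#'
#' @param segset A `segment_set` from [segment_track()].
#' @param params A [consensus_params()].
#' @param caller Override the segment set's caller attribute.
#' @return Region data.frame: `chrom`, `start`, `stop`, `sign`, `mean_log2`,
#'   `n_windows`.
#' @export
threshold_segments <- function(segset, params, caller = attr(segset, "caller")) {
  stopifnot(inherits(params, "consensus_params"))
  if (is.null(caller)) stop("caller not specified")
  th <- if (caller == "A_sliding") c(params$gain_a, params$loss_a)
        else c(params$gain_b, params$loss_b)
  sign <- ifelse(segset$mean_log2 > th[1], "gain",
                 ifelse(segset$mean_log2 < th[2], "loss", "neutral"))
  keep <- which(sign != "neutral")
  if (length(keep) == 0)
    return(data.frame(chrom = character(), start = numeric(), stop = numeric(),
                      sign = character(), mean_log2 = numeric(),
                      n_windows = integer(), stringsAsFactors = FALSE))
  df <- segset[keep, c("chrom", "start", "stop", "start_window",
                       "stop_window", "n_windows", "mean_log2")]
  df$sign <- sign[keep]
  df <- df[order(match(df$chrom, unique(segset$chrom)), df$start), ]
  # merge runs of adjacent same-sign significant segments (gap tolerance 0)
  out <- list()
  cur <- df[1, ]
  if (nrow(df) > 1) for (i in 2:nrow(df)) {
    r <- df[i, ]
    if (r$chrom == cur$chrom && r$sign == cur$sign &&
        r$start_window == cur$stop_window + 1) {
      cur$mean_log2 <- (cur$mean_log2 * cur$n_windows + r$mean_log2 * r$n_windows) /
        (cur$n_windows + r$n_windows)
      cur$stop <- r$stop
      cur$stop_window <- r$stop_window
      cur$n_windows <- cur$n_windows + r$n_windows
    } else {
      out[[length(out) + 1]] <- cur
      cur <- r
    }
  }
  out[[length(out) + 1]] <- cur
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("chrom", "start", "stop", "sign", "mean_log2", "n_windows")]
}

#' Validate caller-A regions against caller-B regions and refine boundaries
#'
#' A caller-A region is validated when the fraction of its bases covered by
#' same-sign caller-B regions (summed over fragmented B calls) strictly
#' exceeds `overlap_min`. Boundaries of a validated region are refined against
#' the single caller-B region contributing the largest overlap: refined start
#' = max of the two starts, refined stop = min of the two stops. Sign
#' agreement is required; a refinement that would produce an empty interval
#' drops the call with a warning rather than emitting an inverted region.
#'
#' @param regions_a,regions_b Region data.frames from [threshold_segments()].
#' @param params A [consensus_params()].
#' @param sample_id Optional sample label carried into the output.
#' @return Validated-CNV data.frame sorted by (chrom, start): `chrom`,
#'   `start`, `stop`, `sign`, `overlap`, plus source coordinates
#'   `a_start`, `a_stop`, `b_start`, `b_stop` and `sample_id`.
#' @export
validate_and_refine <- function(regions_a, regions_b, params = consensus_params(),
                                sample_id = NA_character_) {
  stopifnot(inherits(params, "consensus_params"))
  empty <- data.frame(chrom = character(), start = numeric(), stop = numeric(),
                      sign = character(), overlap = numeric(),
                      a_start = numeric(), a_stop = numeric(),
                      b_start = numeric(), b_stop = numeric(),
                      sample_id = character(), stringsAsFactors = FALSE)
  if (is.null(regions_a) || nrow(regions_a) == 0 ||
      is.null(regions_b) || nrow(regions_b) == 0) return(empty)
  out <- list()
  for (i in seq_len(nrow(regions_a))) {
    a <- regions_a[i, ]
    frac <- overlap_fraction(a[, c("chrom", "start", "stop", "sign")], regions_b)
    if (frac <= params$overlap_min) next
    b <- regions_b[regions_b$chrom == a$chrom & regions_b$sign == a$sign, ,
                   drop = FALSE]
    ov <- pmin(b$stop, a$stop) - pmax(b$start, a$start)
    b <- b[which.max(ov), ]
    start <- max(a$start, b$start)
    stop <- min(a$stop, b$stop)
    if (start >= stop) {
      warning("refined region empty for ", a$chrom, ":", a$start, "-", a$stop,
              "; call dropped")
      next
    }
    cnv <- data.frame(chrom = a$chrom, start = start, stop = stop,
                      sign = a$sign, overlap = frac,
                      a_start = a$start, a_stop = a$stop,
                      b_start = b$start, b_stop = b$stop,
                      sample_id = sample_id, stringsAsFactors = FALSE)
    # containment assertion: refined interval inside both sources
    stopifnot(cnv$start >= cnv$a_start, cnv$stop <= cnv$a_stop,
              cnv$start >= cnv$b_start, cnv$stop <= cnv$b_stop)
    out[[length(out) + 1]] <- cnv
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), ]
  rownames(res) <- NULL
  res
}

#' Percent of genome windows aberrant in a sample
#'
#' Counts fixed-grid windows overlapped (by at least one base) by any
#' validated CNV, as a percentage of the grid's unmasked windows.
#'
#' @param validated Validated-CNV data.frame for one sample.
#' @param grid The fixed `window_grid`.
#' @param unmasked Logical vector of evaluable windows (default: all).
#' @return Percentage in \[0, 100\].
#' @export
aberrant_fraction <- function(validated, grid, unmasked = NULL) {
  if (is.null(unmasked)) unmasked <- rep(TRUE, nrow(grid))
  denom <- sum(unmasked)
  if (denom == 0) stop("no unmasked windows")
  if (is.null(validated) || nrow(validated) == 0) return(0)
  hit <- rep(FALSE, nrow(grid))
  for (i in seq_len(nrow(validated))) {
    v <- validated[i, ]
    hit <- hit | (grid$chrom == v$chrom & grid$start < v$stop & grid$stop > v$start)
  }
  100 * sum(hit & unmasked) / denom
}
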