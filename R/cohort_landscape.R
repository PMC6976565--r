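#' Build the cohort samples-by-windows state matrix
#'
#' Each fixed-grid window is marked `"gain"` or `"loss"` for a sample iff it
#' is overlapped (by at least one base) by a validated CNV of that sign, else
#' `"neutral"`. Overlapping opposite-sign calls hitting the same window in one
#' sample indicate an upstream inconsistency and raise an error.
#'
#' @param validated_by_sample Named list (by sample id) of validated-CNV
#'   data.frames, or one combined data.frame with a `sample_id` column.
#' @param grid The fixed `window_grid`.
#' @return A `cohort_state_matrix`: character matrix samples x windows with
#'   values in \{gain, loss, neutral\}; attribute `grid`.
#' @export
build_state_matrix <- function(validated_by_sample, grid) {
  if (is.data.frame(validated_by_sample)) {
    validated_by_sample <- split(validated_by_sample,
                                 validated_by_sample$sample_id)
  }
  ids <- names(validated_by_sample)
  if (is.null(ids)) stop("sample ids required")
  m <- matrix("neutral", nrow = length(ids), ncol = nrow(grid),
              dimnames = list(ids, NULL))
  for (s in ids) {
    v <- validated_by_sample[[s]]
    if (is.null(v) || nrow(v) == 0) next
    for (i in seq_len(nrow(v))) {
      hit <- which(grid$chrom == v$chrom[i] & grid$start < v$stop[i] &
                     grid$stop > v$start[i])
      clash <- hit[m[s, hit] != "neutral" & m[s, hit] != v$sign[i]]
      if (length(clash) > 0)
        stop("conflicting gain/loss calls in sample ", s, " at window(s) ",
             paste(clash, collapse = ","))
      m[s, hit] <- v$sign[i]
    }
  }
  structure(m, grid = grid, class = c("cohort_state_matrix", "matrix"))
}

#' Per-window cohort gain/loss frequencies
#'
#' @param matrix_ A `cohort_state_matrix`.
#' @return data.frame with `chrom`, `start`, `stop`, `gain_freq`, `loss_freq`
#'   (carrier count / n samples, each in \[0, 1\]).
#' @export
frequency_track <- function(matrix_) {
  if (nrow(matrix_) == 0) stop("empty cohort")
  grid <- attr(matrix_, "grid")
  data.frame(chrom = grid$chrom, start = grid$start, stop = grid$stop,
             gain_freq = colMeans(matrix_ == "gain"),
             loss_freq = colMeans(matrix_ == "loss"),
             stringsAsFactors = FALSE)
}

#' Common CNG/CNL segments by frequency-changepoints
#'
#' Per sign, a common segment is a maximal run of contiguous windows (within
#' one chromosome) whose cohort frequency strictly exceeds `threshold`. The
#' carrier set of a segment is the samples aberrant (with that sign) in at
#' least half of the segment's windows.
#'
#' @param matrix_ A `cohort_state_matrix`.
#' @param threshold Frequency threshold (default 0.2, i.e. the ">20%" rule).
#' @return data.frame: `chrom`, `start`, `stop`, `variant_type`
#'   (`"CNG"`/`"CNL"`), `frequency` (mean over the segment's windows),
#'   `n_carriers`, `carriers` (comma-joined ids), `windows` (list column of
#'   window indices).
#' @export
common_segments <- function(matrix_, threshold = 0.2) {
  grid <- attr(matrix_, "grid")
  freq <- frequency_track(matrix_)
  out <- list()
  for (sg in c("gain", "loss")) {
    f <- if (sg == "gain") freq$gain_freq else freq$loss_freq
    super <- f > threshold
    # maximal runs, split at chromosome boundaries
    run_id <- cumsum(c(TRUE, diff(as.integer(factor(grid$chrom, levels = unique(grid$chrom)))) != 0 |
                         diff(super) != 0))
    for (r in unique(run_id[super])) {
      w <- which(run_id == r & super)
      if (length(w) == 0) next
      carrier_frac <- rowMeans(matrix_[, w, drop = FALSE] == sg)
      carriers <- rownames(matrix_)[carrier_frac >= 0.5]
      out[[length(out) + 1]] <- data.frame(
        chrom = grid$chrom[w[1]], start = grid$start[w[1]],
        stop = grid$stop[w[length(w)]],
        variant_type = if (sg == "gain") "CNG" else "CNL",
        frequency = mean(f[w]), n_carriers = length(carriers),
        carriers = paste(carriers, collapse = ","),
        stringsAsFactors = FALSE)
      out[[length(out)]]$windows <- I(list(w))
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), start = numeric(), stop = numeric(),
                      variant_type = character(), frequency = numeric(),
                      n_carriers = integer(), carriers = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$variant_type, match(res$chrom, unique(grid$chrom)), res$start), ]
  rownames(res) <- NULL
  res
}

#' Per-sample CNV burden scores vs the cohort median
#'
#' For each sample, the percentage of windows aberrant overall, gained, and
#' lost; each percentage is classed `"high"` iff it is >= the cohort median of
#' that percentage (so at least half the cohort is always high).
#'
#' @param matrix_ A `cohort_state_matrix` with >= 2 samples.
#' @return data.frame: `sample_id`, `pct_aberrant`, `pct_gain`, `pct_loss`,
#'   `score_cnv`, `score_cng`, `score_cnl`.
#' @export
cnv_score <- function(matrix_) {
  if (nrow(matrix_) < 2) stop("need >= 2 samples")
  pct_ab <- 100 * rowMeans(matrix_ != "neutral")
  pct_g <- 100 * rowMeans(matrix_ == "gain")
  pct_l <- 100 * rowMeans(matrix_ == "loss")
  cls <- function(x) ifelse(x >= stats::median(x), "high", "low")
  data.frame(sample_id = rownames(matrix_),
             pct_aberrant = pct_ab, pct_gain = pct_g, pct_loss = pct_l,
             score_cnv = cls(pct_ab), score_cng = cls(pct_g),
             score_cnl = cls(pct_l),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Maximum segment mean log2 over a gene region
#'
#' The gene-level log2 used e.g. by the HER2 rescue rule: the maximum
#' `mean_log2` among segments overlapping the gene interval. A gain anywhere
#' in the gene body counts as the gene's gain.
#'
#' @param segset A `segment_set`.
#' @param chrom,start,stop Gene coordinates (bp, half-open).
#' @return The maximum mean log2, or `NA` if no segment overlaps (masked).
#' @export
gene_region_log2 <- function(segset, chrom, start, stop) {
  grid <- attr(segset, "grid")
  if (!is.null(grid) && !chrom %in% grid$chrom) stop("gene chromosome off layout")
  hit <- segset$chrom == chrom & segset$start < stop & segset$stop > start
  if (!any(hit)) return(NA_real_)
  max(segset$mean_log2[hit])
}

#' Annotate regions with intersecting genes from a BED file
#'
#' @param regions Region data.frame (`chrom`, `start`, `stop`).
#' @param gene_bed Path to a BED file (chrom, start, stop, name), or a
#'   data.frame with those columns.
#' @return The regions with a `genes` column (comma-joined names of genes
#'   whose half-open interval intersects the region).
#' @export
annotate_regions <- function(regions, gene_bed) {
  genes <- if (is.character(gene_bed)) {
    g <- utils::read.table(gene_bed, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
    if (ncol(g) < 4) stop("malformed gene BED: need chrom, start, stop, name")
    stats::setNames(g[, 1:4], c("chrom", "start", "stop", "name"))
  } else gene_bed
  regions$genes <- vapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    hit <- genes$chrom == r$chrom & genes$start < r$stop & genes$stop > r$start
    paste(genes$name[hit], collapse = ",")
  }, character(1))
  regions
}

#' Write common segments as BED5 (name = CNG/CNL, score = frequency x 1000)
#' @param segments Output of [common_segments()].
#' @param path Output path.
#' @export
write_common_segments_bed <- function(segments, path) {
  df <- data.frame(segments$chrom, segments$start, segments$stop,
                   segments$variant_type, round(segments$frequency * 1000))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}
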