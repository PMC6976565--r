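# Independent oracles used across the suite. All are brute-force or
# enumeration based and deliberately share no code with the implementation.

# exhaustive penalized-segmentation optimum: enumerate every admissible
# breakpoint subset for short vectors
exhaustive_seg_optimum <- function(values, gamma, kmin = 1) {
  n <- length(values)
  seg_cost <- function(idx) {
    seg <- values[idx]
    sum((seg - mean(seg))^2)
  }
  best <- Inf
  positions <- if (n >= 2) 2:n else integer(0)
  for (m in 0:length(positions)) {
    combos <- if (m == 0) list(integer(0)) else
      utils::combn(positions, m, simplify = FALSE)
    for (bp in combos) {
      starts <- c(1L, bp)
      stops <- c(bp - 1L, n)
      if (any(stops - starts + 1L < kmin)) next
      cost <- sum(vapply(seq_along(starts),
                         function(k) seg_cost(starts[k]:stops[k]), numeric(1))) +
        gamma * m
      if (cost < best) best <- cost
    }
  }
  best
}

# base-by-base one-directional same-sign coverage fraction (integer coords)
overlap_fraction_bruteforce <- function(a, b_set) {
  bases <- seq(a$start, a$stop - 1)
  covered <- vapply(bases, function(p) {
    any(b_set$chrom == a$chrom & b_set$sign == a$sign &
          b_set$start <= p & p < b_set$stop)
  }, logical(1))
  mean(covered)
}

# hand risk-set enumeration of the two-group Mantel-Cox statistic
logrank_oracle_2group <- function(time, event, group) {
  g <- as.integer(factor(group))
  stopifnot(length(unique(g)) == 2)
  times <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# empirical survival function (no censoring): share of subjects with T > t
empirical_survival <- function(time, t) mean(time > t)

# brute-force run scan for super-threshold frequency runs of one sign
common_runs_bruteforce <- function(freq, chrom, threshold) {
  runs <- list()
  cur <- NULL
  for (i in seq_along(freq)) {
    if (freq[i] > threshold && (is.null(cur) || chrom[i] == cur$chrom)) {
      if (is.null(cur)) cur <- list(from = i, to = i, chrom = chrom[i])
      else cur$to <- i
    } else {
      if (!is.null(cur)) runs[[length(runs) + 1]] <- cur
      cur <- if (freq[i] > threshold) list(from = i, to = i, chrom = chrom[i]) else NULL
    }
  }
  if (!is.null(cur)) runs[[length(runs) + 1]] <- cur
  runs
}

# small two-chromosome layout used by many unit tests
toy_layout <- function() genome_layout(c("chr1", "chr2"), c(10e6, 6e6))

# wrap a numeric vector as a ratio_track on a given grid
as_track <- function(values, grid, caller = "B_fixed", id = "T1") {
  structure(data.frame(chrom = grid$chrom, start = grid$start,
                       stop = grid$stop, log2 = values),
            grid = grid, caller = caller, sample_id = id,
            class = c("ratio_track", "data.frame"))
}
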