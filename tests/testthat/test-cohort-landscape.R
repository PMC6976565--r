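# 10-window single-chromosome grid and a state matrix built from calls
grid10 <- build_grid(genome_layout("c1", 20e6), 2e6, "fixed")

test_that("state matrix marks overlapped windows per sign", {
  v <- list(S1 = data.frame(chrom = "c1", start = 0, stop = 4e6, sign = "gain"),
            S2 = data.frame(chrom = "c1", start = 10e6, stop = 14e6,
                            sign = "loss"),
            S3 = data.frame(chrom = character(), start = numeric(),
                            stop = numeric(), sign = character()))
  m <- build_state_matrix(v, grid10)
  expect_equal(unname(m["S1", 1:2]), c("gain", "gain"))
  expect_true(all(m["S1", 3:10] == "neutral"))
  expect_equal(unname(m["S2", 6:7]), c("loss", "loss"))
  expect_true(all(m["S3", ] == "neutral"))
  # conflicting signs in one sample/window raise
  bad <- list(S1 = data.frame(chrom = "c1", start = c(0, 2e6),
                              stop = c(4e6, 6e6), sign = c("gain", "loss")))
  expect_error(build_state_matrix(bad, grid10), "conflict")
})

test_that("frequency track counts carriers per window and sign", {
  v <- list(S1 = data.frame(chrom = "c1", start = 0, stop = 4e6, sign = "gain"),
            S2 = data.frame(chrom = "c1", start = 0, stop = 2e6, sign = "gain"),
            S3 = data.frame(chrom = "c1", start = 0, stop = 2e6, sign = "loss"),
            S4 = data.frame(chrom = character(), start = numeric(),
                            stop = numeric(), sign = character()),
            S5 = data.frame(chrom = character(), start = numeric(),
                            stop = numeric(), sign = character()))
  f <- frequency_track(build_state_matrix(v, grid10))
  expect_equal(f$gain_freq[1], 0.4)
  expect_equal(f$loss_freq[1], 0.2)  # gain and loss can coexist at a window
  expect_equal(f$gain_freq[2], 0.2)
  expect_error(frequency_track(build_state_matrix(list(), grid10)))
})

test_that("common segments are maximal strict-threshold runs", {
  # craft a matrix directly: 10 samples, gains over chosen windows
  mk <- function(freqs) {
    m <- matrix("neutral", 10, length(freqs))
    for (j in seq_along(freqs)) if (freqs[j] > 0) m[seq_len(freqs[j] * 10), j] <- "gain"
    structure(m, grid = grid10[seq_along(freqs), ],
              dimnames = list(sprintf("S%02d", 1:10), NULL),
              class = c("cohort_state_matrix", "matrix"))
  }
  cs1 <- common_segments(mk(c(0.1, 0.4, 0.4, 0.1)), 0.2)
  expect_equal(nrow(cs1), 1)
  expect_equal(c(cs1$start, cs1$stop), c(2e6, 6e6))
  expect_equal(cs1$variant_type, "CNG")
  # all exactly at threshold: strict > excludes
  expect_equal(nrow(common_segments(mk(rep(0.2, 4)), 0.2)), 0)
  # broken run yields two segments
  cs3 <- common_segments(mk(c(0.4, 0.1, 0.4)), 0.2)
  expect_equal(nrow(cs3), 2)
})

test_that("common segments split at chromosome boundaries and find carriers", {
  lay <- genome_layout(c("c1", "c2"), c(4e6, 4e6))
  g <- build_grid(lay, 2e6, "fixed")
  m <- matrix("neutral", 4, 4,
              dimnames = list(paste0("S", 1:4), NULL))
  m[1:2, 1:4] <- "loss"  # superthreshold run spanning the chrom boundary
  sm <- structure(m, grid = g, class = c("cohort_state_matrix", "matrix"))
  cs <- common_segments(sm, 0.2)
  expect_equal(nrow(cs), 2)  # split at c1/c2 boundary
  expect_equal(cs$chrom, c("c1", "c2"))
  expect_equal(cs$n_carriers, c(2, 2))
  expect_equal(cs$carriers, c("S1,S2", "S1,S2"))
})

test_that("completeness: emitted segments exactly cover superthreshold windows", {
  set.seed(55)
  for (i in 1:30) {
    nw <- sample(6:14, 1)
    lay <- genome_layout(c("c1", "c2"), c(2e6 * ceiling(nw / 2), 2e6 * floor(nw / 2)))
    g <- build_grid(lay, 2e6, "fixed")
    ns <- 8
    m <- matrix(sample(c("gain", "loss", "neutral"), ns * nrow(g), TRUE,
                       prob = c(0.25, 0.25, 0.5)), ns, nrow(g),
                dimnames = list(paste0("S", 1:ns), NULL))
    sm <- structure(m, grid = g, class = c("cohort_state_matrix", "matrix"))
    cs <- common_segments(sm, 0.2)
    for (sg in c("gain", "loss")) {
      freq <- colMeans(m == sg)
      runs <- common_runs_bruteforce(freq, g$chrom, 0.2)
      got <- cs[cs$variant_type == (if (sg == "gain") "CNG" else "CNL"), ]
      expect_equal(nrow(got), length(runs))
      if (length(runs)) {
        expect_equal(sort(got$start),
                     sort(g$start[vapply(runs, `[[`, 1, "from")]))
        expect_equal(sort(got$stop),
                     sort(g$stop[vapply(runs, `[[`, 1, "to")]))
      }
    }
  }
})

test_that("common segments are invariant to sample order", {
  set.seed(56)
  m <- matrix(sample(c("gain", "neutral"), 60, TRUE), 6, 10,
              dimnames = list(paste0("S", 1:6), NULL))
  sm <- structure(m, grid = grid10, class = c("cohort_state_matrix", "matrix"))
  perm <- sample(1:6)
  sm2 <- structure(m[perm, ], grid = grid10,
                   class = c("cohort_state_matrix", "matrix"))
  a <- common_segments(sm); b <- common_segments(sm2)
  expect_equal(a[, c("chrom", "start", "stop", "variant_type", "frequency")],
               b[, c("chrom", "start", "stop", "variant_type", "frequency")])
})

test_that("cnv_score classes follow the >= median rule", {
  mk_pct <- function(pcts) {
    # pcts out of 100 windows aberrant
    m <- matrix("neutral", length(pcts), 100)
    for (i in seq_along(pcts)) if (pcts[i] > 0) m[i, seq_len(pcts[i])] <- "gain"
    g <- build_grid(genome_layout("c1", 200e6), 2e6, "fixed")
    structure(m, grid = g, dimnames = list(paste0("S", seq_along(pcts)), NULL),
              class = c("cohort_state_matrix", "matrix"))
  }
  s1 <- cnv_score(mk_pct(c(1, 2, 3, 4)))
  expect_equal(s1$score_cnv, c("low", "low", "high", "high"))  # median 2.5
  s2 <- cnv_score(mk_pct(c(1, 2, 2, 5)))
  expect_equal(s2$score_cnv, c("low", "high", "high", "high"))  # ties at median are high
  s3 <- cnv_score(mk_pct(c(3, 3, 3)))
  expect_true(all(s3$score_cnv == "high"))
  # never fewer than half the cohort high
  set.seed(3)
  s4 <- cnv_score(mk_pct(sample(0:50, 9)))
  expect_gte(sum(s4$score_cnv == "high"), ceiling(9 / 2))
  expect_error(cnv_score(mk_pct(5)), "2 samples")
})

test_that("gene-level log2 is the max over overlapping segments", {
  ss <- structure(data.frame(chrom = c("E1", "E1", "E1"),
                             start = c(0, 30e6, 50e6),
                             stop = c(30e6, 50e6, 63e6),
                             start_window = c(1, 16, 26),
                             stop_window = c(15, 25, 32),
                             n_windows = c(15, 10, 7),
                             mean_log2 = c(0.1, 0.55, -0.2)),
                  class = c("segment_set", "data.frame"))
  her2 <- her2_gene_region()
  expect_equal(gene_region_log2(ss, her2$chrom, her2$start, her2$stop), 0.55)
  # gene spanning two segments takes the larger mean
  expect_equal(gene_region_log2(ss, "E1", 29e6, 31e6), 0.55)
  # no overlapping segment: undefined, not zero
  expect_true(is.na(gene_region_log2(ss, "E1", 70e6, 71e6)))
})

test_that("annotate_regions intersects half-open gene intervals", {
  genes <- data.frame(chrom = "B1", start = c(5e6, 23e6), stop = c(6e6, 24e6),
                      name = c("GENE1", "GENE2"))
  reg <- data.frame(chrom = "B1", start = 1e6, stop = 23e6)
  ann <- annotate_regions(reg, genes)
  expect_equal(ann$genes, "GENE1")  # GENE2 abuts the region end: excluded
  f <- tempfile()
  write.table(genes, f, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  ann2 <- annotate_regions(reg, f)
  expect_equal(ann2$genes, "GENE1")
  empty <- annotate_regions(reg, genes[0, ])
  expect_equal(empty$genes, "")
})
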