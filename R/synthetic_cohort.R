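#' Default planted CNV panel
#'
#' Recurrent aberrations at the scale typical of feline mammary carcinoma
#' cohorts (validated CNVs average ~23 Mb): a whole-chromosome E3 gain,
#' arm-sized gain on B4, losses on proximal B1, distal D1 and distal X.
#' Amplitudes are on the log2 copy-ratio scale of the pure tumour (+0.7 ~
#' between one and two extra copies; -1 = one-copy loss). All regions span at
#' least ~21 sliding bins so that both caller styles (including the
#' kmin = 20 sliding caller) can delimit them.
#'
#' @return data.frame: `name`, `chrom`, `start`, `stop`, `amplitude`,
#'   `carrier_prob`.
#' @export
default_planted_cnvs <- function() {
  data.frame(
    name = c("cng_E3", "cng_B4", "cnl_B1", "cnl_D1", "cnl_X"),
    chrom = c("E3", "B4", "B1", "D1", "X"),
    start = c(0, 0, 0, 40e6, 104e6),
    stop = c(43e6, 28e6, 22e6, 96e6, 130e6),
    amplitude = c(0.7, 0.7, -1.0, -1.0, -1.0),
    carrier_prob = c(0.42, 0.40, 0.30, 0.25, 0.20),
    stringsAsFactors = FALSE)
}

#' Synthetic-cohort configuration
#'
#' Defines the joint generative model the pipeline is validated against:
#' negative-binomial tumour/normal window counts with planted copy-number
#' segments diluted by tumour purity, exponential recurrence/death hazards
#' log-linear in carried aberrations, and subtype-conditional
#' immunohistochemistry.
#'
#' @param n_samples Cohort size (default 33 cats).
#' @param layout `genome_layout` (default [feline_layout()]).
#' @param window_size Analysis window in bp (default 2 Mb; counts are
#'   simulated on half-window base bins so both caller grids can be formed).
#' @param mean_reads_per_window Expected read count per fixed window.
#' @param dispersion Negative-binomial overdispersion, expressed as the
#'   extra-Poisson variance fraction: variance = (1 + dispersion) * mu
#'   (so 0.1 = 10% more variance than Poisson, realistic for read depth in
#'   megabase windows); must be > 0.
#' @param planted_cnvs data.frame as [default_planted_cnvs()]; optional
#'   per-subtype carrier probabilities via columns `carrier_prob_<subtype>`.
#' @param tumor_purity Tumour cell fraction, scalar or per sample.
#' @param baseline_hazard Recurrence hazard (events/month) for a
#'   no-aberration sample.
#' @param cnv_log_hazard_ratios Named vector (by planted CNV name) of log
#'   hazard ratios on recurrence; unnamed CNVs have coefficient 0.
#' @param death_gap_rate Rate of the exponential recurrence-to-death gap.
#' @param nontumor_death_rate Hazard of death from non-tumour causes.
#' @param followup_months Administrative follow-up horizon (default 24).
#' @param subtype_probs Named probabilities over the six subtypes.
#' @param marker_noise Marker-generation noise in \[0, 1\] (0 = rule-exact).
#' @param seed Integer seed; the whole cohort is reproducible given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 33,
                       layout = feline_layout(),
                       window_size = 2e6,
                       mean_reads_per_window = 100,
                       dispersion = 0.1,
                       planted_cnvs = default_planted_cnvs(),
                       tumor_purity = 0.8,
                       baseline_hazard = 0.04,
                       cnv_log_hazard_ratios = c(cng_B4 = log(4), cnl_D1 = log(2)),
                       death_gap_rate = 0.25,
                       nontumor_death_rate = 0.005,
                       followup_months = 24,
                       subtype_probs = c(LA = 0.23, LB_fHER2_neg = 0.12,
                                         LB_fHER2_pos = 0.04, fHER2_pos = 0.04,
                                         normal_like_TN = 0.35,
                                         basal_like_TN = 0.22),
                       marker_noise = 0,
                       seed = 1L) {
  stopifnot(n_samples >= 1, dispersion > 0, mean_reads_per_window > 0,
            baseline_hazard >= 0, nontumor_death_rate >= 0,
            death_gap_rate > 0, followup_months > 0,
            all(tumor_purity >= 0 & tumor_purity <= 1),
            marker_noise >= 0, marker_noise <= 1)
  if (nrow(planted_cnvs) > 0) {
    stopifnot(all(planted_cnvs$carrier_prob >= 0 & planted_cnvs$carrier_prob <= 1),
              all(planted_cnvs$chrom %in% layout$chrom),
              all(planted_cnvs$stop <= chrom_length(layout, planted_cnvs$chrom)))
  }
  subtype_probs <- subtype_probs / sum(subtype_probs)
  structure(list(n_samples = as.integer(n_samples), layout = layout,
                 window_size = window_size,
                 mean_reads_per_window = mean_reads_per_window,
                 dispersion = dispersion, planted_cnvs = planted_cnvs,
                 tumor_purity = rep_len(tumor_purity, n_samples),
                 baseline_hazard = baseline_hazard,
                 cnv_log_hazard_ratios = cnv_log_hazard_ratios,
                 death_gap_rate = death_gap_rate,
                 nontumor_death_rate = nontumor_death_rate,
                 followup_months = followup_months,
                 subtype_probs = subtype_probs,
                 marker_noise = marker_noise,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw truth subtypes and planted-CNV carrier status
#'
#' @param config A [sim_config()].
#' @param seed Seed (default derived from `config$seed`).
#' @return List: `subtype` (character, length n), `carriers` (n x k logical
#'   matrix, columns named by CNV), `truth_regions` (per-sample planted
#'   regions with amplitudes), `sample_ids`.
#' @export
simulate_truth <- function(config, seed = config$seed) {
  withr::with_seed(seed, {
    n <- config$n_samples
    ids <- sprintf("S%03d", seq_len(n))
    subtype <- sample(names(config$subtype_probs), n, replace = TRUE,
                      prob = config$subtype_probs)
    pc <- config$planted_cnvs
    k <- nrow(pc)
    carriers <- matrix(FALSE, n, k,
                       dimnames = list(ids, if (k) pc$name else NULL))
    if (k > 0) for (j in seq_len(k)) {
      prob <- vapply(subtype, function(st) {
        col <- paste0("carrier_prob_", st)
        if (col %in% names(pc) && !is.na(pc[[col]][j])) pc[[col]][j]
        else pc$carrier_prob[j]
      }, numeric(1))
      carriers[, j] <- stats::runif(n) < prob
    }
    truth <- NULL
    if (k > 0) {
      rows <- which(carriers, arr.ind = TRUE)
      if (nrow(rows) > 0) {
        truth <- data.frame(sample_id = ids[rows[, 1]],
                            name = pc$name[rows[, 2]],
                            chrom = pc$chrom[rows[, 2]],
                            start = pc$start[rows[, 2]],
                            stop = pc$stop[rows[, 2]],
                            amplitude = pc$amplitude[rows[, 2]],
                            sign = ifelse(pc$amplitude[rows[, 2]] > 0,
                                          "gain", "loss"),
                            stringsAsFactors = FALSE)
        truth <- truth[order(truth$sample_id, truth$chrom, truth$start), ]
        rownames(truth) <- NULL
      }
    }
    if (is.null(truth))
      truth <- data.frame(sample_id = character(), name = character(),
                          chrom = character(), start = numeric(),
                          stop = numeric(), amplitude = numeric(),
                          sign = character(), stringsAsFactors = FALSE)
    # conflicting-sign overlap within a sample is a config error
    if (nrow(truth) > 1) for (s in unique(truth$sample_id)) {
      tr <- truth[truth$sample_id == s, ]
      if (nrow(tr) > 1) for (i in 1:(nrow(tr) - 1)) for (j in (i + 1):nrow(tr)) {
        if (tr$chrom[i] == tr$chrom[j] && tr$start[i] < tr$stop[j] &&
            tr$stop[i] > tr$start[j] && tr$sign[i] != tr$sign[j])
          stop("overlapping planted regions with conflicting signs in ", s)
      }
    }
    list(sample_ids = ids, subtype = subtype, carriers = carriers,
         truth_regions = truth)
  })
}

#' Simulate tumour and normal-reference window counts
#'
#' Counts are drawn on half-window base bins (width `window_size / 2`) so
#' that both the fixed and the sliding caller grids can be aggregated from
#' one coherent realization. For a base bin inside a planted region of log2
#' amplitude A in a sample of purity p, the expected count is
#' `mu0 * (p * 2^A + (1 - p))`; elsewhere `mu0 = mean_reads_per_window / 2`.
#' Counts are negative-binomial with variance `(1 + dispersion) * mu`. Two
#' normal reference tracks are drawn at deliberately different library sizes
#' (scale 1 and 1.25) to exercise library-size normalization downstream.
#'
#' @param config A [sim_config()].
#' @param truth Output of [simulate_truth()].
#' @param seed Seed (default `config$seed + 1`).
#' @return List: `base_grid`, `tumor` (base bins x samples count matrix),
#'   `normals` (base bins x 2).
#' @export
simulate_counts <- function(config, truth, seed = config$seed + 1L) {
  base_grid <- build_grid(config$layout, config$window_size / 2, "fixed")
  nb <- nrow(base_grid)
  n <- config$n_samples
  mu0 <- config$mean_reads_per_window / 2
  d <- config$dispersion
  withr::with_seed(seed, {
    tumor <- matrix(0L, nb, n, dimnames = list(NULL, truth$sample_ids))
    for (s in seq_len(n)) {
      mu <- rep(mu0, nb)
      tr <- truth$truth_regions
      tr <- tr[tr$sample_id == truth$sample_ids[s], , drop = FALSE]
      if (nrow(tr) > 0) for (i in seq_len(nrow(tr))) {
        w <- region_to_windows(tr[i, c("chrom", "start", "stop")], base_grid)
        p <- config$tumor_purity[s]
        f <- p * 2^tr$amplitude[i] + (1 - p)
        # same-sign overlap: the stronger aberration wins
        cur <- mu[w] / mu0
        mu[w] <- mu0 * ifelse(abs(log2(pmax(cur, 1e-9))) >= abs(log2(f)), cur, f)
      }
      # size = mu/d gives variance mu + mu^2/(mu/d) = (1 + d) * mu
      tumor[, s] <- stats::rnbinom(nb, size = mu / d, mu = mu)
    }
    normals <- cbind(stats::rnbinom(nb, size = mu0 / d, mu = mu0),
                     stats::rnbinom(nb, size = mu0 * 1.25 / d, mu = mu0 * 1.25))
    colnames(normals) <- c("N1", "N2")
    list(base_grid = base_grid, tumor = tumor, normals = normals)
  })
}

#' Combine two normal reference tracks
#'
#' Each reference is library-size normalized (divided by its total), the two
#' relative tracks are averaged, and the average is rescaled to the mean
#' library size, giving one count-scale reference track.
#'
#' @param normals Matrix with one column per reference.
#' @return Numeric vector, one value per window.
#' @export
combine_normals <- function(normals) {
  rel <- sweep(normals, 2, colSums(normals), "/")
  rowMeans(rel) * mean(colSums(normals))
}

#' Aggregate base-bin counts onto a (fixed or sliding) window grid
#'
#' A base bin contributes to every target window containing its midpoint; on
#' the sliding grid interior bins therefore contribute to two overlapping
#' windows, which is exactly the double-counting a sliding-window caller
#' performs.
#'
#' @param base_counts Numeric vector on `base_grid`, or a matrix with one
#'   column per sample.
#' @param base_grid,target_grid `window_grid` objects on the same layout.
#' @return Numeric vector on `target_grid` (or matrix, windows x samples).
#' @export
aggregate_to_grid <- function(base_counts, base_grid, target_grid) {
  mat <- is.matrix(base_counts)
  if ((if (mat) nrow(base_counts) else length(base_counts)) != nrow(base_grid))
    stop("base_counts must match base_grid")
  # within a chromosome base midpoints are sorted, so each target window
  # selects a contiguous run of base bins
  nt <- nrow(target_grid)
  lo <- integer(nt); hi <- integer(nt)
  mid <- (base_grid$start + base_grid$stop) / 2
  for (ch in unique(target_grid$chrom)) {
    bi <- which(base_grid$chrom == ch)
    ti <- which(target_grid$chrom == ch)
    m <- mid[bi]
    lo[ti] <- bi[1] + findInterval(target_grid$start[ti], m, left.open = TRUE)
    hi[ti] <- bi[1] - 1 + findInterval(target_grid$stop[ti], m, left.open = TRUE)
  }
  if (!mat) {
    cs <- c(0, cumsum(base_counts))
    out <- cs[hi + 1] - cs[lo]
  } else {
    cs <- rbind(0, apply(base_counts, 2, cumsum))
    out <- cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]
    dimnames(out) <- list(NULL, colnames(base_counts))
  }
  out
}

#' Simulate recurrence, death and censoring
#'
#' Recurrence time is exponential with hazard `baseline_hazard *
#' exp(sum of log hazard ratios of carried planted CNVs)`; tumour death
#' follows recurrence after an exponential gap; an independent exponential
#' non-tumour death time competes. All times are subject to administrative
#' censoring at `followup_months`.
#'
#' @param config A [sim_config()].
#' @param truth Output of [simulate_truth()].
#' @param seed Seed (default `config$seed + 2`).
#' @return data.frame: `sample_id`, `recurrence_months`, `death_months`,
#'   `death_cause` (`"tumour"`/`"non_tumour"`/NA), `alive_at_end`,
#'   `true_log_hazard`.
#' @export
simulate_outcomes <- function(config, truth, seed = config$seed + 2L) {
  n <- config$n_samples
  beta <- config$cnv_log_hazard_ratios
  lp <- numeric(n)
  if (length(beta) > 0 && ncol(truth$carriers) > 0) {
    for (nm in names(beta)) {
      if (nm %in% colnames(truth$carriers))
        lp <- lp + beta[[nm]] * truth$carriers[, nm]
    }
  }
  fup <- config$followup_months
  withr::with_seed(seed, {
    hz <- config$baseline_hazard * exp(lp)
    r_time <- ifelse(hz > 0, stats::rexp(n, rate = pmax(hz, 1e-300)), Inf)
    r_time[hz == 0] <- Inf
    gap <- stats::rexp(n, rate = config$death_gap_rate)
    d_time <- r_time + gap
    nt <- if (config$nontumor_death_rate > 0)
      stats::rexp(n, rate = config$nontumor_death_rate) else rep(Inf, n)
    rec <- rep(NA_real_, n); dth <- rep(NA_real_, n)
    cause <- rep(NA_character_, n); alive <- rep(TRUE, n)
    for (i in seq_len(n)) {
      if (min(r_time[i], nt[i]) > fup) next            # censored alive
      if (nt[i] <= r_time[i]) {                        # non-tumour death first
        dth[i] <- nt[i]; cause[i] <- "non_tumour"; alive[i] <- FALSE
      } else {
        rec[i] <- r_time[i]
        dm <- min(d_time[i], nt[i])
        if (dm <= fup) {
          dth[i] <- dm
          cause[i] <- if (d_time[i] <= nt[i]) "tumour" else "non_tumour"
          alive[i] <- FALSE
        }
      }
    }
    data.frame(sample_id = truth$sample_ids, recurrence_months = rec,
               death_months = dth, death_cause = cause, alive_at_end = alive,
               true_log_hazard = lp, stringsAsFactors = FALSE)
  })
}

# subtype-conditional marker centers: er%, er int, pr%, pr int, fher2 ihc,
# ck5/6 %, ki-67 %
.marker_centers <- function() {
  rbind(LA            = c(80, 3, 70, 3, 0, 0, 8),
        LB_fHER2_neg  = c(70, 3, 50, 2, 1, 0, 30),
        LB_fHER2_pos  = c(60, 2, 40, 2, 3, 0, 35),
        fHER2_pos     = c(0, 0, 0, 0, 3, 0, 40),
        normal_like_TN = c(0, 0, 0, 0, 0, 0, 30),
        basal_like_TN = c(0, 0, 0, 0, 0, 40, 50))
}

#' Simulate immunohistochemistry and histopathology per sample
#'
#' Marker values are drawn from subtype-conditional distributions centred on
#' rule-consistent values, so at `marker_noise = 0` [classify_clinical()]
#' recovers every truth subtype exactly. Noise perturbs percentages
#' (Gaussian, SD `20 * noise`) and flips the fHER2 IHC score with probability
#' `noise / 2`. Mitotic counts are Poisson around the Ki-67 level, and three
#' grading-system labels are derived from the mitotic count with per-system
#' jitter (to exercise the agreement statistics).
#'
#' @param config A [sim_config()].
#' @param truth Output of [simulate_truth()].
#' @param seed Seed (default `config$seed + 3`).
#' @return data.frame of marker and histopathology columns.
#' @export
simulate_markers <- function(config, truth, seed = config$seed + 3L) {
  n <- config$n_samples
  ctr <- .marker_centers()
  noise <- config$marker_noise
  withr::with_seed(seed, {
    m <- ctr[truth$subtype, , drop = FALSE]
    jit <- function(x) pmin(100, pmax(0, x + stats::rnorm(n, 0, 20 * noise)))
    er_p <- jit(m[, 1]); pr_p <- jit(m[, 3])
    ck <- jit(m[, 6]); ki <- jit(m[, 7])
    ihc <- m[, 5]
    flip <- stats::runif(n) < noise / 2
    ihc[flip] <- sample(0:3, sum(flip), replace = TRUE)
    mitotic <- stats::rpois(n, lambda = 2 + ki)
    grade_of <- function(cnt) ifelse(cnt < 10, "I", ifelse(cnt < 35, "II", "III"))
    jitter_count <- function() pmax(0, mitotic + stats::rpois(n, 3) - 3)
    data.frame(sample_id = truth$sample_ids,
               er_percent = er_p, er_intensity = m[, 2],
               pr_percent = pr_p, pr_intensity = m[, 4],
               fher2_ihc = as.integer(ihc),
               ck56_percent = ck, ki67_percent = ki,
               mitotic_count = mitotic,
               grade_EE = grade_of(mitotic),
               grade_MMEE = grade_of(jitter_count()),
               grade_Mills = grade_of(jitter_count()),
               tumour_size = round(exp(stats::rnorm(n, log(2.5), 0.4)), 1),
               node_positive = stats::runif(n) < 0.4,
               truth_subtype = truth$subtype,
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

#' Simulate a complete cohort
#'
#' Runs [simulate_truth()], [simulate_counts()], [simulate_outcomes()] and
#' [simulate_markers()] under seeds derived from `config$seed` and assembles
#' the result. The whole object is byte-identical across runs for a fixed
#' configuration.
#'
#' @param config A [sim_config()].
#' @return An `fmc_cohort` list: `config`, `base_grid`, `fixed_grid`,
#'   `sliding_grid`, `tumor_counts`, `normal_counts`, `truth` (subtype,
#'   carriers, truth_regions), `clinical` (markers + outcomes).
#' @export
simulate_cohort <- function(config) {
  truth <- simulate_truth(config)
  cnt <- simulate_counts(config, truth)
  out <- simulate_outcomes(config, truth)
  mrk <- simulate_markers(config, truth)
  clinical <- merge(mrk, out, by = "sample_id", sort = FALSE)
  clinical <- clinical[match(truth$sample_ids, clinical$sample_id), ]
  rownames(clinical) <- NULL
  structure(list(config = config,
                 base_grid = cnt$base_grid,
                 fixed_grid = build_grid(config$layout, config$window_size, "fixed"),
                 sliding_grid = build_grid(config$layout, config$window_size, "sliding"),
                 tumor_counts = cnt$tumor,
                 normal_counts = cnt$normals,
                 truth = truth,
                 clinical = clinical),
            class = "fmc_cohort")
}

#' Write a cohort to disk (counts TSV, truth BED, clinical TSV)
#' @param cohort An `fmc_cohort`.
#' @param dir Output directory (created if absent).
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  counts <- data.frame(cohort$base_grid[, c("chrom", "start", "stop")],
                       cohort$tumor_counts, cohort$normal_counts,
                       check.names = FALSE)
  utils::write.table(counts, file.path(dir, "window_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr <- cohort$truth$truth_regions
  write_regions_bed(tr[, c("chrom", "start", "stop", "sign", "sample_id")],
                    file.path(dir, "truth_regions.bed"))
  utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
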