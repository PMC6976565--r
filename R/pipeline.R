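#' Default segmentation parameters for the two caller styles
#'
#' Caller A (CNV-seq style, sliding ~half-window-step bins): gamma = 20,
#' kmin = 20. Caller B (CNVKit style, fixed bins): gamma = 10, kmin = 5 —
#' the sliding caller has roughly twice the bins, hence the stiffer penalty.
#'
#' @return Named list of [seg_params()]: `A` and `B`.
#' @export
default_seg_params <- function() {
  list(A = seg_params(gamma = 20, kmin = 20),
       B = seg_params(gamma = 10, kmin = 5))
}

#' Call validated CNVs for one sample
#'
#' The dual-caller consensus procedure: build the caller-A (sliding) and
#' caller-B (fixed, mode-centred) log2 tracks from base-bin counts, segment
#' each with its gamma/kmin, threshold into significant regions, validate
#' caller-A regions by >80% same-sign overlap with caller-B regions, and
#' refine boundaries to max-start/min-stop.
#'
#' @param tumor_base,normal_base Base-bin count vectors (see
#'   [simulate_counts()]; real data can be supplied on the same half-window
#'   bins).
#' @param base_grid Base-bin `window_grid`.
#' @param fixed_grid,sliding_grid Caller grids (built from the same layout).
#' @param seg_pars Named list `A`, `B` of [seg_params()].
#' @param cons_pars A [consensus_params()].
#' @param sample_id Sample label.
#' @return List: `validated` (data.frame), `regions_a`, `regions_b`,
#'   `segs_a`, `segs_b`, `track_a`, `track_b`.
#' @export
call_sample <- function(tumor_base, normal_base, base_grid, fixed_grid,
                        sliding_grid, seg_pars = default_seg_params(),
                        cons_pars = consensus_params(),
                        sample_id = NA_character_) {
  call_sample_tracks(aggregate_to_grid(tumor_base, base_grid, sliding_grid),
                     aggregate_to_grid(normal_base, base_grid, sliding_grid),
                     aggregate_to_grid(tumor_base, base_grid, fixed_grid),
                     aggregate_to_grid(normal_base, base_grid, fixed_grid),
                     fixed_grid, sliding_grid, seg_pars, cons_pars, sample_id)
}

# consensus calling from already-aggregated per-grid counts
call_sample_tracks <- function(t_slide, n_slide, t_fix, n_fix, fixed_grid,
                               sliding_grid, seg_pars = default_seg_params(),
                               cons_pars = consensus_params(),
                               sample_id = NA_character_) {
  track_a <- compute_log2_track(t_slide, n_slide, sliding_grid, "A_sliding",
                                sample_id)
  track_b <- compute_log2_track(t_fix, n_fix, fixed_grid, "B_fixed", sample_id)
  track_b <- centre_mode(track_b)
  segs_a <- segment_track(track_a, seg_pars$A)
  segs_b <- segment_track(track_b, seg_pars$B)
  regions_a <- threshold_segments(segs_a, cons_pars)
  regions_b <- threshold_segments(segs_b, cons_pars)
  validated <- validate_and_refine(regions_a, regions_b, cons_pars, sample_id)
  list(validated = validated, regions_a = regions_a, regions_b = regions_b,
       segs_a = segs_a, segs_b = segs_b, track_a = track_a, track_b = track_b)
}

#' Run the CNV consensus pipeline over a cohort
#'
#' Calls every sample with [call_sample()], assembles the cohort state
#' matrix, frequency track, common segments, burden scores and per-sample
#' HER2 gene-level log2 (from the caller-B segments, for the IHC-2+ rescue).
#'
#' @param cohort An `fmc_cohort` from [simulate_cohort()], or a list with the
#'   same count/grid fields built from real data.
#' @param seg_pars,cons_pars Parameters as in [call_sample()].
#' @return List: `validated` (named list per sample), `calls` (combined
#'   data.frame), `state_matrix`, `freq`, `common`, `scores`, `her2_log2`
#'   (named vector), `aberrant_pct` (named vector).
#' @export
run_cnv_pipeline <- function(cohort, seg_pars = default_seg_params(),
                             cons_pars = consensus_params()) {
  normal_base <- combine_normals(cohort$normal_counts)
  ids <- colnames(cohort$tumor_counts)
  t_slide <- aggregate_to_grid(cohort$tumor_counts, cohort$base_grid,
                               cohort$sliding_grid)
  t_fix <- aggregate_to_grid(cohort$tumor_counts, cohort$base_grid,
                             cohort$fixed_grid)
  n_slide <- aggregate_to_grid(normal_base, cohort$base_grid,
                               cohort$sliding_grid)
  n_fix <- aggregate_to_grid(normal_base, cohort$base_grid, cohort$fixed_grid)
  her2 <- her2_gene_region()
  validated <- list(); her2_log2 <- stats::setNames(rep(NA_real_, length(ids)), ids)
  for (s in ids) {
    res <- call_sample_tracks(t_slide[, s], n_slide, t_fix[, s], n_fix,
                              cohort$fixed_grid, cohort$sliding_grid,
                              seg_pars, cons_pars, s)
    validated[[s]] <- res$validated
    her2_log2[s] <- gene_region_log2(res$segs_b, her2$chrom, her2$start,
                                     her2$stop)
  }
  state <- build_state_matrix(validated, cohort$fixed_grid)
  calls <- do.call(rbind, validated)
  rownames(calls) <- NULL
  list(validated = validated,
       calls = calls,
       state_matrix = state,
       freq = frequency_track(state),
       common = common_segments(state),
       scores = cnv_score(state),
       her2_log2 = her2_log2,
       aberrant_pct = vapply(validated, aberrant_fraction,
                             numeric(1), grid = cohort$fixed_grid))
}
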