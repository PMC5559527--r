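#' Default analysis thresholds
#'
#' All cutoffs used by the pipeline, collected in one list so that every stage
#' reads its defaults from a single place and a run configuration can override
#' any of them. The defaults are the published conventions for multi-region
#' myeloma heterogeneity analysis:
#'
#' * `vaf_call_min` (0.05): a variant must reach 5% VAF in at least one sample
#'   of the patient to be analyzed at all.
#' * `depth_min_all` (20): total coverage must exceed 20x in **all** samples of
#'   the patient (strict inequality).
#' * `detect_min_reads` (2) / `noise_max_reads` (1): two alt reads score a
#'   mutation as detected; a single read is treated as noise ("negative").
#' * `negative_min_depth` (50): an unshared call additionally requires >= 50
#'   total reads at the locus in the negative sample.
#' * `het_ccf_min` (0.2): heterogeneous labels (unshared / shared-diff) require
#'   a cancer clonal fraction of at least 0.2 on the positive (larger) side.
#' * `clonal_ccf` (0.8): CCF >= 0.8 flags a mutation as clonal in a sample.
#' * `shared_diff_fold` (3): ubiquitous mutations with >= three-fold CCF
#'   difference between paired samples are shared-differential.
#' * `cna_size_min` (1e6) / `cna_clonal_min` (0.8) / `cna_overlap_min` (0.5):
#'   unshared-CNA counting uses events > 1 Mb, clonal in at least one sample,
#'   matched across samples by reciprocal 50% overlap.
#' * `neutral_window` ((0.12, 0.24), exclusive) / `neutral_min_snvs` (12) /
#'   `neutral_r2` (0.98): the neutral-evolution test window, eligibility floor
#'   and verdict threshold.
#' * `gep70_threshold` (0.66): GEP70 scores at or above this are high-risk.
#' * `max_c_mode` (`"major"`): multiplicity candidates run from 1 to the
#'   major-allele copy number (falls back to total copy number when the minor
#'   allele count is unavailable).
#' * `eps_vaf` (1e-6): expected VAFs are clipped into `[eps, 1-eps]` before
#'   binomial likelihood evaluation.
#' * `seg_fallback_diploid` (TRUE): positions not covered by any copy-number
#'   segment are treated as diploid (with a warning) rather than erroring.
#'
#' @return Named list of thresholds.
#' @export
default_thresholds <- function() {
  list(
    vaf_call_min       = 0.05,
    depth_min_all      = 20L,
    detect_min_reads   = 2L,
    noise_max_reads    = 1L,
    negative_min_depth = 50L,
    het_ccf_min        = 0.2,
    clonal_ccf         = 0.8,
    shared_diff_fold   = 3,
    cna_size_min       = 1e6,
    cna_clonal_min     = 0.8,
    cna_overlap_min    = 0.5,
    neutral_window     = c(0.12, 0.24),
    neutral_min_snvs   = 12L,
    neutral_r2         = 0.98,
    gep70_threshold    = 0.66,
    max_c_mode         = "major",
    eps_vaf            = 1e-6,
    seg_fallback_diploid = TRUE
  )
}

#' Merge user thresholds over the defaults
#'
#' @param overrides Named list of threshold overrides (may be `NULL`).
#' @param require_complete If `TRUE`, error when a known threshold is missing
#'   after merging (used by [run_pipeline()] startup validation).
#' @return Complete threshold list.
#' @export
merge_thresholds <- function(overrides = NULL, require_complete = TRUE) {
  defaults <- default_thresholds()
  if (is.null(overrides)) return(defaults)
  stopifnot(is.list(overrides))
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown threshold field(s): ", paste(unknown, collapse = ", "))
  }
  out <- modifyList(defaults, overrides)
  if (require_complete) {
    missing <- names(defaults)[vapply(names(defaults), function(nm) {
      is.null(out[[nm]]) || anyNA(out[[nm]])
    }, logical(1))]
    if (length(missing) > 0L) {
      stop("missing or NA threshold field(s): ", paste(missing, collapse = ", "))
    }
  }
  out
}
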