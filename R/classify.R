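# Variant-inclusion filters and between-site mutation classification.
# A mutation is "detected" in a sample at >= 2 alt reads and "negative" at
# <= 1 alt read (a single read is noise). Per sample pair:
#   * detected in one / negative in the other, positive-side CCF >= 0.2 and
#     negative-side depth >= 50            -> unshared (clonal/subclonal by CCF 0.8)
#   * detected in both, >= 3-fold CCF difference, larger CCF >= 0.2 -> shared_diff
#   * detected in both otherwise           -> shared
#   * a heterogeneous pattern failing one of its floors
#                                          -> unclassified_heterogeneous
#     (still counted in the mutation total, never in the heterogeneous counts)

#' Apply the variant-inclusion filters
#'
#' Keeps variants that (i) reach the VAF call threshold (default 5%) in at
#' least one sample of the patient, (ii) have coverage exceeding
#' `depth_min_all` (default 20x, strict) in *all* samples of the patient, and
#' (iii) fall outside an optional blacklist of regions (e.g. immunoglobulin
#' loci). Rows with missing depth cause their variant to be dropped.
#'
#' @param variants Long table with columns `sample, chrom, pos, alt_reads,
#'   depth` and a `mutation_id` column identifying the variant across samples
#'   (created from `chrom:pos:alt_allele` when absent). Multiple patients are
#'   filtered independently when a `patient` column is present.
#' @param blacklist Optional data frame of regions `chrom, start, end`
#'   (1-based inclusive), e.g. from [read_bed()].
#' @param thresholds Threshold list, see [default_thresholds()].
#' @return The filtered table, with attribute `filter_counts` recording rows
#'   in/out and variants dropped per rule.
#' @export
filter_variants <- function(variants, blacklist = NULL,
                            thresholds = default_thresholds()) {
  th <- merge_thresholds(thresholds)
  v <- variants
  if (!"mutation_id" %in% names(v)) {
    alt <- if ("alt_allele" %in% names(v)) v$alt_allele else ""
    v$mutation_id <- paste(v$chrom, v$pos, alt, sep = ":")
  }
  if (!"patient" %in% names(v)) v$patient <- "patient1"
  key <- paste(v$patient, v$mutation_id, sep = "\r")

  depth_bad <- is.na(v$depth) | v$depth <= th$depth_min_all
  vaf <- ifelse(is.na(v$depth) | v$depth == 0, 0, v$alt_reads / v$depth)
  vaf_ok <- !is.na(vaf) & vaf >= th$vaf_call_min

  drop_depth <- unique(key[depth_bad])
  keep_vaf <- unique(key[vaf_ok])

  in_blacklist <- rep(FALSE, nrow(v))
  if (!is.null(blacklist) && nrow(blacklist) > 0L) {
    q <- GenomicRanges::GRanges(as.character(v$chrom),
                                IRanges::IRanges(v$pos, v$pos))
    b <- GenomicRanges::GRanges(as.character(blacklist$chrom),
                                IRanges::IRanges(blacklist$start, blacklist$end))
    in_blacklist <- suppressWarnings(IRanges::overlapsAny(q, b))
  }
  drop_bl <- unique(key[in_blacklist])

  keep <- !(key %in% drop_depth) & (key %in% keep_vaf) & !(key %in% drop_bl)
  out <- v[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_counts") <- list(
    rows_in = nrow(v), rows_out = nrow(out),
    variants_in = length(unique(key)),
    variants_out = length(unique(key[keep])),
    dropped_low_depth = sum(unique(key) %in% drop_depth),
    dropped_low_vaf = sum(!(unique(key) %in% keep_vaf)),
    dropped_blacklist = sum(unique(key) %in% drop_bl)
  )
  out
}

#' Minimum detectable VAF (and CCF) at a given depth
#'
#' With a detection floor of `detect_min_reads` alt reads (default 2; a single
#' read is noise), the smallest detectable VAF at total depth `d` is
#' `detect_min_reads / d` — 4% at the 50x minimum coverage, ~0.4% at 540x.
#' [min_detectable_ccf()] converts this to a CCF floor through the
#' mutation-copy-number equation: 8% for a diploid locus at purity 1 and
#' multiplicity 1 at 50x.
#'
#' @param depth Total read depth(s), `>= 1`.
#' @param detect_min_reads Detection floor in alt reads.
#' @return Minimum detectable VAF as a fraction.
#' @export
min_detectable_vaf <- function(depth, detect_min_reads = 2L) {
  stopifnot(all(depth >= 1))
  detect_min_reads / depth
}

#' @rdname min_detectable_vaf
#' @param purity Tumor purity in `(0, 1]`.
#' @param n_locus_total Tumor total copy number at the locus.
#' @param n_chr Chromosome multiplicity of the mutation.
#' @export
min_detectable_ccf <- function(depth, detect_min_reads = 2L, purity = 1,
                               n_locus_total = 2, n_chr = 1) {
  vaf <- min_detectable_vaf(depth, detect_min_reads)
  mutation_copy_number(vaf, purity, n_locus_total) / n_chr
}

#' Classify mutations between one pair of samples
#'
#' Vectorized over mutations: `a` and `b` are aligned per-sample call rows for
#' the same mutations (same order), as produced by [compute_ccf()]. Labels are
#' mutually exclusive and exhaustive over evaluable mutations; mutations
#' negative in both samples of the pair are not evaluable for this pair.
#'
#' @param a,b Data frames with columns `alt_reads, depth, ccf` (one row per
#'   mutation, aligned).
#' @param thresholds Threshold list, see [default_thresholds()].
#' @return Data frame with `label` (`shared`, `shared_diff`, `unshared`,
#'   `unclassified_heterogeneous`, `not_evaluable`), `clonality` (`clonal` /
#'   `subclonal` for unshared, by positive-sample CCF), `ccf_a`, `ccf_b` and a
#'   machine-readable `reason` trace.
#' @export
classify_pair <- function(a, b, thresholds = default_thresholds()) {
  th <- merge_thresholds(thresholds)
  stopifnot(nrow(a) == nrow(b))
  n <- nrow(a)
  det_a <- !is.na(a$alt_reads) & a$alt_reads >= th$detect_min_reads
  det_b <- !is.na(b$alt_reads) & b$alt_reads >= th$detect_min_reads
  neg_a <- !is.na(a$alt_reads) & a$alt_reads <= th$noise_max_reads
  neg_b <- !is.na(b$alt_reads) & b$alt_reads <= th$noise_max_reads

  label <- rep("not_evaluable", n)
  clonality <- rep(NA_character_, n)
  reason <- rep("", n)

  # non-ubiquitous pattern: detected on one side, negative on the other
  one_sided <- (det_a & neg_b) | (det_b & neg_a)
  if (any(one_sided)) {
    pos_is_a <- det_a & neg_b
    ccf_pos <- ifelse(pos_is_a, a$ccf, b$ccf)
    depth_neg <- ifelse(pos_is_a, b$depth, a$depth)
    ok_ccf <- !is.na(ccf_pos) & ccf_pos >= th$het_ccf_min
    ok_depth <- !is.na(depth_neg) & depth_neg >= th$negative_min_depth
    uns <- one_sided & ok_ccf & ok_depth
    label[uns] <- "unshared"
    clonality[uns] <- ifelse(ccf_pos[uns] >= th$clonal_ccf, "clonal", "subclonal")
    reason[uns] <- "one_sided;ccf_pos>=het_ccf_min;neg_depth>=negative_min_depth"
    fail <- one_sided & !(ok_ccf & ok_depth)
    label[fail] <- "unclassified_heterogeneous"
    reason[fail] <- paste0("one_sided",
                           ifelse(!ok_ccf[fail], ";ccf_pos<het_ccf_min", ""),
                           ifelse(!ok_depth[fail], ";neg_depth<negative_min_depth", ""))
  }

  # ubiquitous pattern: detected in both samples
  both <- det_a & det_b
  if (any(both)) {
    lo <- pmin(a$ccf, b$ccf)
    hi <- pmax(a$ccf, b$ccf)
    fold <- ifelse(lo > 0, hi / lo, ifelse(hi > 0, Inf, 1))
    big_fold <- !is.na(fold) & fold >= th$shared_diff_fold
    hi_ok <- !is.na(hi) & hi >= th$het_ccf_min
    sd_i <- both & big_fold & hi_ok
    label[sd_i] <- "shared_diff"
    reason[sd_i] <- "both_detected;fold>=shared_diff_fold;ccf_max>=het_ccf_min"
    uh_i <- both & big_fold & !hi_ok
    label[uh_i] <- "unclassified_heterogeneous"
    reason[uh_i] <- "both_detected;fold>=shared_diff_fold;ccf_max<het_ccf_min"
    sh_i <- both & !big_fold
    label[sh_i] <- "shared"
    reason[sh_i] <- "both_detected;fold<shared_diff_fold"
  }

  # intermediate evidence (possible only when detect/noise floors leave a gap)
  gap <- !one_sided & !both & !(neg_a & neg_b)
  label[gap] <- "unclassified_heterogeneous"
  reason[gap] <- "intermediate_evidence"
  reason[label == "not_evaluable"] <- "negative_in_both"

  data.frame(label = label, clonality = clonality,
             ccf_a = a$ccf, ccf_b = b$ccf, reason = reason,
             stringsAsFactors = FALSE)
}

# heterogeneity precedence used to reduce multi-pair patients to one label
.label_rank <- c(unshared = 4, shared_diff = 3,
                 unclassified_heterogeneous = 2, shared = 1, not_evaluable = 0)

#' Classify all mutations of one patient across its sample pairs
#'
#' Runs [classify_pair()] for every unordered pair of the patient's samples
#' and reduces each mutation to a single patient-level label using the
#' precedence unshared > shared_diff > unclassified_heterogeneous > shared
#' (the "most heterogeneous" pair wins). For unshared, clonality is taken from
#' the selected pair.
#'
#' @param calls Per-mutation per-sample table from [compute_ccf()], for one
#'   patient, with a `mutation_id` column.
#' @param thresholds Threshold list.
#' @return List with `per_pair` (all pairwise classifications, long) and
#'   `per_mutation` (one row per mutation: `mutation_id, label, clonality`).
#' @export
classify_patient <- function(calls, thresholds = default_thresholds()) {
  stopifnot("mutation_id" %in% names(calls))
  samples <- sort(unique(calls$sample))
  if (length(samples) < 2L) stop("need at least two samples to classify")
  muts <- unique(calls$mutation_id)
  wide <- function(s) {
    sub <- calls[calls$sample == s, , drop = FALSE]
    sub[match(muts, sub$mutation_id), c("alt_reads", "depth", "ccf"), drop = FALSE]
  }
  per_pair <- list()
  best <- data.frame(mutation_id = muts,
                     label = "not_evaluable", clonality = NA_character_,
                     stringsAsFactors = FALSE)
  for (i in seq_len(length(samples) - 1L)) {
    for (j in seq(i + 1L, length(samples))) {
      cl <- classify_pair(wide(samples[i]), wide(samples[j]), thresholds)
      cl <- cbind(data.frame(mutation_id = muts,
                             sample_a = samples[i], sample_b = samples[j],
                             stringsAsFactors = FALSE), cl)
      per_pair[[length(per_pair) + 1L]] <- cl
      upgrade <- .label_rank[cl$label] > .label_rank[best$label]
      best$label[upgrade] <- cl$label[upgrade]
      best$clonality[upgrade] <- cl$clonality[upgrade]
    }
  }
  list(per_pair = do.call(rbind, per_pair), per_mutation = best)
}

#' Per-patient heterogeneity summary
#'
#' Counts and proportions of unshared (clonal / subclonal) and shared-diff
#' mutations. The denominator is the number of evaluable mutations: all
#' classified mutations plus unclassified-heterogeneous ones (which count
#' toward the total but never toward a heterogeneous class). With a zero
#' denominator the proportions are `NA` (undefined), not 0.
#'
#' @param per_mutation One-row-per-mutation classification, from
#'   [classify_patient()].
#' @param patient Patient identifier for the output row.
#' @return One-row data frame of counts and proportions.
#' @export
patient_summary <- function(per_mutation, patient = "patient1") {
  lab <- per_mutation$label
  evaluable <- lab != "not_evaluable"
  n_total <- sum(evaluable)
  n_uns <- sum(lab == "unshared")
  n_uns_clonal <- sum(lab == "unshared" & per_mutation$clonality == "clonal",
                      na.rm = TRUE)
  n_sd <- sum(lab == "shared_diff")
  n_sh <- sum(lab == "shared")
  n_uh <- sum(lab == "unclassified_heterogeneous")
  prop <- function(k) if (n_total == 0L) NA_real_ else k / n_total
  data.frame(
    patient = patient,
    n_total = n_total,
    n_shared = n_sh,
    n_shared_diff = n_sd,
    n_unshared = n_uns,
    n_unshared_clonal = n_uns_clonal,
    n_unshared_subclonal = n_uns - n_uns_clonal,
    n_unclassified_heterogeneous = n_uh,
    prop_unshared = prop(n_uns),
    prop_unshared_clonal = prop(n_uns_clonal),
    prop_unshared_subclonal = prop(n_uns - n_uns_clonal),
    prop_shared_diff = prop(n_sd),
    stringsAsFactors = FALSE
  )
}
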