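# Cancer clonal fraction estimation from read counts, purity and local copy
# number. The chain is: observed VAF -> mutation copy number (n_mut) ->
# chromosome multiplicity (n_chr, binomial maximum likelihood) -> CCF =
# min(1, n_mut / n_chr).

#' Mutation copy number from VAF, purity and locus copy number
#'
#' Converts an observed variant allele frequency into the expected number of
#' mutated-allele copies per tumor cell:
#' \deqn{n_{mut} = f_s \cdot \frac{1}{p} \left[ p\, n^t_{locus} + 2 (1 - p) \right]}
#' where \eqn{f_s} is the VAF, \eqn{p} the tumor purity and
#' \eqn{n^t_{locus}} the tumor total copy number at the locus. Germline copy
#' number is fixed at 2 in the \eqn{2(1-p)} term, including on sex chromosomes
#' (a documented limitation). No capping is applied at this stage.
#'
#' @param vaf Observed VAF(s) in `[0, 1]`.
#' @param purity Tumor purity in `(0, 1]` (recycled).
#' @param n_locus_total Tumor total copy number at the locus (recycled).
#' @return Numeric vector of mutation copy numbers.
#' @examples
#' mutation_copy_number(0.5, 1, 2)     # 1: pure diploid heterozygous
#' mutation_copy_number(0.25, 0.5, 3)  # 1.25
#' @export
mutation_copy_number <- function(vaf, purity, n_locus_total) {
  stopifnot(is.numeric(vaf), is.numeric(purity), is.numeric(n_locus_total))
  if (any(vaf < 0 | vaf > 1, na.rm = TRUE)) stop("vaf must lie in [0, 1]")
  if (any(purity <= 0 | purity > 1, na.rm = TRUE)) stop("purity must lie in (0, 1]")
  vaf * (1 / purity) * (purity * n_locus_total + 2 * (1 - purity))
}

#' Expected VAF of a mutation present on `c` chromosome copies
#'
#' The inverse of [mutation_copy_number()]: for a mutation carried at cancer
#' clonal fraction `ccf` on `n_chr` of the `n_locus_total` tumor copies,
#' \deqn{E[f_s] = \frac{ccf \cdot n_{chr} \cdot p}{p\, n^t_{locus} + 2(1 - p)}.}
#' Used both by the multiplicity assignment (with `ccf = 1`) and by the
#' read-count simulator.
#'
#' @param ccf Cancer clonal fraction(s) in `[0, 1]`.
#' @param n_chr Chromosome multiplicity (copies carrying the mutation).
#' @param purity Tumor purity in `(0, 1]`.
#' @param n_locus_total Tumor total copy number at the locus.
#' @return Expected VAF(s).
#' @export
expected_vaf <- function(ccf, n_chr, purity, n_locus_total) {
  ccf * n_chr * purity / (purity * n_locus_total + 2 * (1 - purity))
}

#' Assign chromosome multiplicity by binomial maximum likelihood
#'
#' Compares the observed alt-read count to the expectation were the mutation
#' carried on 1, 2, ..., `max_c` chromosome copies and returns the multiplicity
#' with the maximum binomial likelihood. Expected VAFs are clipped into
#' `[eps, 1 - eps]` so that near-fixed variants never receive a zero
#' likelihood. Ties break toward the smaller multiplicity (the conservative
#' choice: it never deflates the CCF).
#'
#' @param alt Alt read count(s).
#' @param depth Total read depth(s), `>= 1`.
#' @param purity Tumor purity in `(0, 1]`.
#' @param n_locus_total Tumor total copy number at the locus.
#' @param max_c Largest candidate multiplicity, `>= 1` (recycled). Typically
#'   the major-allele copy number.
#' @param eps Clipping bound for expected VAFs.
#' @return Integer vector of assigned multiplicities.
#' @examples
#' assign_multiplicity(70, 100, purity = 1, n_locus_total = 4, max_c = 3)  # 3
#' @export
assign_multiplicity <- function(alt, depth, purity, n_locus_total, max_c,
                                eps = 1e-6) {
  stopifnot(all(depth >= 1), all(max_c >= 1))
  n <- max(length(alt), length(depth), length(purity),
           length(n_locus_total), length(max_c))
  if (length(alt) == 0L) return(integer(0))
  alt <- rep_len(alt, n); depth <- rep_len(depth, n)
  purity <- rep_len(purity, n)
  n_locus_total <- rep_len(n_locus_total, n)
  max_c <- rep_len(as.integer(max_c), n)

  out <- integer(n)
  cmax <- max(max_c)
  # candidate-by-candidate log-likelihood matrix; max_c is small (<= copy number)
  ll <- matrix(-Inf, nrow = n, ncol = cmax)
  for (c_i in seq_len(cmax)) {
    active <- max_c >= c_i
    f <- expected_vaf(1, c_i, purity[active], n_locus_total[active])
    f <- pmin(pmax(f, eps), 1 - eps)
    ll[active, c_i] <- dbinom(alt[active], depth[active], f, log = TRUE)
  }
  degenerate <- !is.finite(apply(ll, 1L, max))
  if (any(degenerate)) {
    warning(sum(degenerate),
            " site(s) had zero likelihood for every candidate multiplicity; ",
            "assigned n_chr = 1")
    ll[degenerate, 1L] <- 0
  }
  # which.max on each row: first (smallest c) maximizer wins ties
  out <- apply(ll, 1L, which.max)
  as.integer(out)
}

#' Per-mutation, per-sample CCF table
#'
#' Computes VAF, mutation copy number, chromosome multiplicity and cancer
#' clonal fraction for every row of a long variant table. Locus copy-number
#' state is looked up in the per-sample segmented profile; positions not
#' covered by any segment are treated as diploid with a warning (or rejected
#' when `thresholds$seg_fallback_diploid` is `FALSE`). Loci with total copy
#' number 0 but a positive VAF are flagged inconsistent (`ccf = NA`): a
#' variant cannot be observed on a homozygously deleted locus.
#'
#' @param variants Long data frame, one row per mutation per sample, with
#'   columns `patient, sample, chrom, pos, ref, alt_allele, alt_reads, depth`
#'   (a `mutation_id` column is carried through if present).
#' @param contexts Data frame with columns `sample, purity` (and optionally
#'   `site`, `mean_depth`).
#' @param segs Data frame of copy-number segments with columns
#'   `sample, chrom, start, end, total_cn, minor_cn` (1-based inclusive), as
#'   read by [read_seg()].
#' @param thresholds Threshold list, see [default_thresholds()].
#' @return The input table with added columns `vaf, purity, n_locus, n_major,
#'   n_mut, n_chr, ccf, clonal, cn_inconsistent`.
#' @export
compute_ccf <- function(variants, contexts, segs,
                        thresholds = default_thresholds()) {
  need <- c("sample", "chrom", "pos", "alt_reads", "depth")
  stopifnot(all(need %in% names(variants)),
            all(c("sample", "purity") %in% names(contexts)))
  th <- merge_thresholds(thresholds)

  v <- variants
  v$vaf <- ifelse(v$depth > 0, v$alt_reads / v$depth, NA_real_)
  pu <- setNames(contexts$purity, contexts$sample)
  if (!all(v$sample %in% names(pu))) {
    stop("samples without purity context: ",
         paste(unique(setdiff(v$sample, names(pu))), collapse = ", "))
  }
  v$purity <- unname(pu[v$sample])

  cn <- lookup_locus_cn(v, segs,
                        fallback_diploid = isTRUE(th$seg_fallback_diploid))
  v$n_locus <- cn$total_cn
  v$n_major <- cn$major_cn

  v$cn_inconsistent <- v$n_locus == 0 & v$alt_reads > 0
  ok <- !v$cn_inconsistent & v$n_locus >= 1

  v$n_mut <- NA_real_
  v$n_mut[ok] <- mutation_copy_number(v$vaf[ok], v$purity[ok], v$n_locus[ok])

  max_c <- if (identical(th$max_c_mode, "major")) {
    ifelse(is.na(v$n_major), v$n_locus, v$n_major)
  } else {
    v$n_locus
  }
  max_c <- pmax(1L, as.integer(max_c))

  v$n_chr <- NA_integer_
  if (any(ok)) {
    v$n_chr[ok] <- assign_multiplicity(v$alt_reads[ok], v$depth[ok],
                                       v$purity[ok], v$n_locus[ok],
                                       max_c[ok], eps = th$eps_vaf)
  }
  v$ccf <- pmin(1, v$n_mut / v$n_chr)
  v$clonal <- !is.na(v$ccf) & v$ccf >= th$clonal_ccf
  v
}

# Locus copy-number lookup: per (sample, chrom, pos) find the covering segment.
# Returns total and major (total - minor) copy number; uncovered positions are
# diploid when fallback_diploid, otherwise an error.
lookup_locus_cn <- function(variants, segs, fallback_diploid = TRUE) {
  stopifnot(all(c("sample", "chrom", "start", "end", "total_cn") %in% names(segs)))
  n <- nrow(variants)
  total <- rep(NA_real_, n)
  major <- rep(NA_real_, n)
  has_minor <- "minor_cn" %in% names(segs)
  for (s in unique(variants$sample)) {
    vi <- which(variants$sample == s)
    seg_s <- segs[segs$sample == s, , drop = FALSE]
    if (nrow(seg_s) == 0L) next
    q <- GenomicRanges::GRanges(as.character(variants$chrom[vi]),
                                IRanges::IRanges(variants$pos[vi], variants$pos[vi]))
    subj <- GenomicRanges::GRanges(as.character(seg_s$chrom),
                                   IRanges::IRanges(seg_s$start, seg_s$end))
    hit <- suppressWarnings(
      GenomicRanges::findOverlaps(q, subj, select = "first"))
    covered <- !is.na(hit)
    total[vi[covered]] <- seg_s$total_cn[hit[covered]]
    if (has_minor) {
      major[vi[covered]] <- seg_s$total_cn[hit[covered]] - seg_s$minor_cn[hit[covered]]
    }
  }
  uncovered <- is.na(total)
  if (any(uncovered)) {
    if (!fallback_diploid) {
      stop(sum(uncovered), " variant position(s) not covered by any segment")
    }
    warning(sum(uncovered),
            " variant position(s) not covered by any segment; assuming diploid")
    total[uncovered] <- 2
    major[uncovered] <- 1
  }
  list(total_cn = total, major_cn = major)
}
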