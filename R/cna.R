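# Copy-number discordance between segmented profiles. Segments are reduced to
# events (gain / loss / copy-neutral LOH relative to a diploid baseline);
# events are matched across samples by reciprocal overlap; the unshared-CNA
# count keeps events that are clonal in the sample carrying them, longer than
# the size floor, and present in exactly one profile of the pair.

#' Reduce a segmented copy-number profile to CNA events
#'
#' Adjacent same-chromosome segments with identical `(total_cn, minor_cn)` are
#' merged (clonal fraction combined as a length-weighted mean), then segments
#' deviating from the diploid baseline are labelled: `gain` (total > 2),
#' `loss` (total < 2) or `cnloh` (total = 2, minor = 0).
#'
#' @param seg Data frame with columns `chrom, start, end, total_cn, minor_cn`
#'   and optionally `clonal_fraction` (assumed 1 when absent); coordinates
#'   1-based inclusive.
#' @param baseline Diploid baseline total copy number (2).
#' @return Data frame of events: `chrom, start, end, kind, total_cn, minor_cn,
#'   clonal_fraction, length`.
#' @export
seg_to_events <- function(seg, baseline = 2) {
  stopifnot(all(c("chrom", "start", "end", "total_cn") %in% names(seg)))
  if (!"minor_cn" %in% names(seg)) seg$minor_cn <- NA_real_
  if (!"clonal_fraction" %in% names(seg)) seg$clonal_fraction <- 1
  if (any(seg$end < seg$start)) stop("segment with end < start")
  seg <- seg[order(seg$chrom, seg$start), , drop = FALSE]

  merged <- list()
  cur <- NULL
  for (i in seq_len(nrow(seg))) {
    row <- seg[i, ]
    joinable <- !is.null(cur) &&
      cur$chrom == row$chrom &&
      row$start <= cur$end + 1L &&
      identical(cur$total_cn, row$total_cn) &&
      identical(cur$minor_cn, row$minor_cn)
    if (joinable) {
      w1 <- cur$end - cur$start + 1
      w2 <- row$end - row$start + 1
      cur$clonal_fraction <- (cur$clonal_fraction * w1 + row$clonal_fraction * w2) /
        (w1 + w2)
      cur$end <- max(cur$end, row$end)
    } else {
      if (!is.null(cur)) merged[[length(merged) + 1L]] <- cur
      cur <- row
    }
  }
  if (!is.null(cur)) merged[[length(merged) + 1L]] <- cur
  m <- do.call(rbind, merged)

  kind <- rep(NA_character_, nrow(m))
  kind[m$total_cn > baseline] <- "gain"
  kind[m$total_cn < baseline] <- "loss"
  kind[m$total_cn == baseline & !is.na(m$minor_cn) & m$minor_cn == 0] <- "cnloh"
  ev <- m[!is.na(kind), , drop = FALSE]
  ev$kind <- kind[!is.na(kind)]
  ev$length <- ev$end - ev$start + 1
  rownames(ev) <- NULL
  ev[, c("chrom", "start", "end", "kind", "total_cn", "minor_cn",
         "clonal_fraction", "length")]
}

# reciprocal-overlap sharing: is each event of `ev` matched by a same-kind
# event in `other` with intersection >= overlap_min of both lengths?
.events_shared <- function(ev, other, overlap_min, reciprocal = TRUE) {
  if (nrow(ev) == 0L) return(logical(0))
  shared <- rep(FALSE, nrow(ev))
  if (nrow(other) == 0L) return(shared)
  g1 <- GenomicRanges::GRanges(as.character(ev$chrom),
                               IRanges::IRanges(ev$start, ev$end))
  g2 <- GenomicRanges::GRanges(as.character(other$chrom),
                               IRanges::IRanges(other$start, other$end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(g1, g2))
  if (length(hits) == 0L) return(shared)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(IRanges::ranges(g1)[qi],
                                           IRanges::ranges(g2)[si]))
  same_kind <- ev$kind[qi] == other$kind[si]
  frac_q <- ov / ev$length[qi]
  frac_s <- ov / other$length[si]
  good <- same_kind & frac_q >= overlap_min &
    (!reciprocal | frac_s >= overlap_min)
  shared[unique(qi[good])] <- TRUE
  shared
}

#' Count unshared CNAs between two segmented profiles
#'
#' An event in one profile is *shared* when the other profile contains an
#' event of the same kind overlapping it reciprocally by at least
#' `overlap_min` of each event's length. The unshared-CNA count (delta CNA)
#' keeps events that are private to one profile, longer than `size_min`
#' (strict, default 1 Mb) and clonal (`clonal_fraction >= clonal_min`) in the
#' sample carrying them.
#'
#' @param seg_a,seg_b Segmented profiles (see [seg_to_events()]). A `genome`
#'   attribute, when present on both and different, is an error.
#' @param size_min Minimum event length in bp (strict), default 1e6.
#' @param clonal_min Clonal-fraction floor, default 0.8.
#' @param overlap_min Reciprocal overlap fraction for sharing, default 0.5.
#' @param reciprocal Apply the overlap fraction to both events (default) or
#'   only to the query event.
#' @return List with `delta_cna` (integer count) and `events` (the private
#'   events counted, with a `profile` column `"a"` / `"b"`).
#' @export
unshared_cna_count <- function(seg_a, seg_b, size_min = 1e6, clonal_min = 0.8,
                               overlap_min = 0.5, reciprocal = TRUE) {
  ga <- attr(seg_a, "genome"); gb <- attr(seg_b, "genome")
  if (!is.null(ga) && !is.null(gb) && !identical(ga, gb)) {
    stop("segmented profiles declare different genome builds: ", ga, " vs ", gb)
  }
  ev_a <- seg_to_events(seg_a)
  ev_b <- seg_to_events(seg_b)
  sh_a <- .events_shared(ev_a, ev_b, overlap_min, reciprocal)
  sh_b <- .events_shared(ev_b, ev_a, overlap_min, reciprocal)
  keep_a <- !sh_a & ev_a$length > size_min & ev_a$clonal_fraction >= clonal_min
  keep_b <- !sh_b & ev_b$length > size_min & ev_b$clonal_fraction >= clonal_min
  priv <- rbind(
    if (any(keep_a)) cbind(ev_a[keep_a, , drop = FALSE], profile = "a"),
    if (any(keep_b)) cbind(ev_b[keep_b, , drop = FALSE], profile = "b")
  )
  list(delta_cna = sum(keep_a) + sum(keep_b),
       events = if (is.null(priv)) {
         cbind(ev_a[0, , drop = FALSE], profile = character(0))
       } else priv)
}

#' Flag deletions affecting genes of interest
#'
#' Scans a segmented profile for deletions overlapping gene regions, subject
#' to a resolution-dependent size floor: 10 kb for high-resolution (SNP array)
#' profiles, 1 Mb for WES-only profiles. A deletion is bi-allelic when the
#' overlapping segment has total copy number 0, or when the caller reports a
#' co-occurring mutation in the gene (`mutated_genes`).
#'
#' @param seg Segmented profile data frame.
#' @param gene_regions Data frame `chrom, start, end, gene` (e.g. from
#'   [read_bed()] with a name column).
#' @param size_min Deletion size floor in bp: `1e4` for high-resolution data,
#'   `1e6` for WES-only.
#' @param mutated_genes Character vector of genes with a non-silent mutation
#'   in this sample (used for deletion + mutation bi-allelic calls).
#' @return Data frame `gene, deleted, biallelic, min_total_cn`; zero rows for
#'   an empty `gene_regions`.
#' @export
gene_deletion_check <- function(seg, gene_regions, size_min = 1e4,
                                mutated_genes = character(0)) {
  if (is.null(gene_regions) || nrow(gene_regions) == 0L) {
    return(data.frame(gene = character(0), deleted = logical(0),
                      biallelic = logical(0), min_total_cn = numeric(0)))
  }
  stopifnot(all(c("chrom", "start", "end", "gene") %in% names(gene_regions)))
  ev <- seg_to_events(seg)
  del <- ev[ev$kind == "loss" & ev$length >= size_min, , drop = FALSE]
  out <- data.frame(gene = gene_regions$gene,
                    deleted = FALSE, biallelic = FALSE,
                    min_total_cn = NA_real_, stringsAsFactors = FALSE)
  if (nrow(del) > 0L) {
    gg <- GenomicRanges::GRanges(as.character(gene_regions$chrom),
                                 IRanges::IRanges(gene_regions$start,
                                                  gene_regions$end))
    gd <- GenomicRanges::GRanges(as.character(del$chrom),
                                 IRanges::IRanges(del$start, del$end))
    hits <- suppressWarnings(GenomicRanges::findOverlaps(gg, gd))
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    for (g in unique(qi)) {
      cn <- min(del$total_cn[si[qi == g]])
      out$deleted[g] <- TRUE
      out$min_total_cn[g] <- cn
      out$biallelic[g] <- cn == 0 || out$gene[g] %in% mutated_genes
    }
  }
  out
}
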