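# shared fixture builders: tiny call rows and segmented profiles built in code

call_row <- function(alt, depth, ccf) {
  data.frame(alt_reads = alt, depth = depth, ccf = ccf)
}

# diploid profile over 22 autosomes with optional event rows layered on top
flat_seg <- function(sample = "S1") {
  spatialmm::build_seg_profile(NULL, c(C1 = 1), sample)
}

seg_with_events <- function(events, sample = "S1") {
  # events: data.frame(chrom, start, end, total_cn, minor_cn, clonal_fraction)
  events$clones <- "C1"
  seg <- spatialmm::build_seg_profile(events[, c("chrom", "start", "end",
                                                 "total_cn", "minor_cn",
                                                 "clones")],
                                      c(C1 = 1), sample)
  # build_seg_profile stamps carrier fraction 1; patch in requested fractions
  for (i in seq_len(nrow(events))) {
    hit <- seg$chrom == events$chrom[i] & seg$start == events$start[i] &
      seg$end == events$end[i]
    seg$clonal_fraction[hit] <- events$clonal_fraction[i]
  }
  seg
}
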