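test_that("identical profiles have zero unshared CNAs", {
  ev <- data.frame(chrom = 13, start = 20e6, end = 40e6,
                   total_cn = 1, minor_cn = 0, clonal_fraction = 1)
  a <- seg_with_events(ev, "A")
  b <- seg_with_events(ev, "B")
  expect_equal(unshared_cna_count(a, b)$delta_cna, 0)
})

test_that("a private clonal 20 Mb deletion counts; a 0.5 Mb gain does not", {
  a <- seg_with_events(data.frame(chrom = 13, start = 20e6, end = 40e6 - 1,
                                  total_cn = 1, minor_cn = 0,
                                  clonal_fraction = 1), "A")
  b <- flat_seg("B")
  res <- unshared_cna_count(a, b)
  expect_equal(res$delta_cna, 1)
  expect_identical(res$events$kind, "loss")

  small <- seg_with_events(data.frame(chrom = 2, start = 1e6, end = 1.5e6 - 1,
                                      total_cn = 3, minor_cn = 1,
                                      clonal_fraction = 1), "A")
  expect_equal(unshared_cna_count(small, b)$delta_cna, 0)  # not > 1 Mb
})

test_that("subclonal private events are excluded by the clonality rule", {
  a <- seg_with_events(data.frame(chrom = 5, start = 1e6, end = 60e6,
                                  total_cn = 3, minor_cn = 1,
                                  clonal_fraction = 0.5), "A")
  b <- flat_seg("B")
  expect_equal(unshared_cna_count(a, b)$delta_cna, 0)
  expect_equal(unshared_cna_count(a, b, clonal_min = 0.4)$delta_cna, 1)
})

test_that("delta CNA is symmetric and monotone in the size floor", {
  a <- seg_with_events(data.frame(chrom = c(1, 8), start = c(145e6, 1e6),
                                  end = c(200e6, 3e6),
                                  total_cn = c(3, 1), minor_cn = c(1, 0),
                                  clonal_fraction = 1), "A")
  b <- seg_with_events(data.frame(chrom = 17, start = 1, end = 20e6,
                                  total_cn = 1, minor_cn = 0,
                                  clonal_fraction = 1), "B")
  expect_equal(unshared_cna_count(a, b)$delta_cna,
               unshared_cna_count(b, a)$delta_cna)
  sizes <- c(1e5, 1e6, 1e7, 1e8)
  counts <- vapply(sizes, function(sm) {
    unshared_cna_count(a, b, size_min = sm)$delta_cna
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("reciprocal-overlap sharing matches a per-base bitmap oracle", {
  # toy single-chromosome genome; compare the GRanges route against a
  # brute-force bitmap computation of pairwise intersection fractions
  set.seed(77)
  L <- 1e6
  mk <- function(n, sample) {
    starts <- sort(sample.int(L - 2000, n))
    ends <- pmin(starts + sample.int(200000, n), L)
    kind_cn <- rbind(c(1, 0), c(3, 1))[sample(1:2, n, TRUE), , drop = FALSE]
    data.frame(sample = sample, chrom = 1, start = starts, end = ends,
               total_cn = kind_cn[, 1], minor_cn = kind_cn[, 2],
               clonal_fraction = 1)
  }
  for (rep in 1:5) {
    a <- mk(4, "A"); b <- mk(4, "B")
    ev_a <- seg_to_events(a); ev_b <- seg_to_events(b)
    bitmap <- function(ev) {
      m <- matrix(FALSE, nrow(ev), L)
      for (i in seq_len(nrow(ev))) m[i, ev$start[i]:ev$end[i]] <- TRUE
      m
    }
    ba <- bitmap(ev_a); bb <- bitmap(ev_b)
    shared_oracle <- vapply(seq_len(nrow(ev_a)), function(i) {
      any(vapply(seq_len(nrow(ev_b)), function(j) {
        if (ev_a$kind[i] != ev_b$kind[j]) return(FALSE)
        ov <- sum(ba[i, ] & bb[j, ])
        ov >= 0.5 * sum(ba[i, ]) && ov >= 0.5 * sum(bb[j, ])
      }, logical(1)))
    }, logical(1))
    res <- unshared_cna_count(a, b, size_min = 0)
    n_priv_a <- sum(res$events$profile == "a")
    expect_equal(n_priv_a, sum(!shared_oracle))
  }
})

test_that("mixed genome builds are rejected", {
  a <- flat_seg("A"); b <- flat_seg("B")
  attr(a, "genome") <- "GRCh37"
  attr(b, "genome") <- "GRCh38"
  expect_error(unshared_cna_count(a, b), "genome builds")
})

test_that("gene deletion flags respect resolution floors and bi-allelic rules", {
  genes <- data.frame(chrom = 1, start = 2e6, end = 2.1e6, gene = "CDKN2C")
  # homozygous deletion covering the gene -> bi-allelic
  hom <- seg_with_events(data.frame(chrom = 1, start = 1.5e6, end = 2.5e6,
                                    total_cn = 0, minor_cn = 0,
                                    clonal_fraction = 1), "A")
  r <- gene_deletion_check(hom, genes, size_min = 1e4)
  expect_true(r$deleted && r$biallelic)
  # 8 kb mono-allelic deletion: below the 10 kb hi-res floor and the 1 Mb
  # WES floor alike
  tiny <- seg_with_events(data.frame(chrom = 1, start = 2e6, end = 2e6 + 7999,
                                     total_cn = 1, minor_cn = 0,
                                     clonal_fraction = 1), "A")
  expect_false(gene_deletion_check(tiny, genes, size_min = 1e4)$deleted)
  expect_false(gene_deletion_check(tiny, genes, size_min = 1e6)$deleted)
  # mono-allelic deletion plus reported mutation -> bi-allelic inactivation
  mono <- seg_with_events(data.frame(chrom = 1, start = 1e6, end = 3e6,
                                     total_cn = 1, minor_cn = 0,
                                     clonal_fraction = 1), "A")
  r2 <- gene_deletion_check(mono, genes, size_min = 1e4,
                            mutated_genes = "CDKN2C")
  expect_true(r2$biallelic)
  r3 <- gene_deletion_check(mono, genes, size_min = 1e4)
  expect_true(r3$deleted)
  expect_false(r3$biallelic)
  # empty gene set -> empty result
  expect_equal(nrow(gene_deletion_check(mono, genes[0, ], 1e4)), 0)
})

test_that("adjacent same-state segments merge into one event", {
  seg <- data.frame(sample = "A", chrom = 1,
                    start = c(1, 5e6), end = c(5e6 - 1, 9e6),
                    total_cn = 3, minor_cn = 1, clonal_fraction = 1)
  ev <- seg_to_events(seg)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$length, 9e6)
  expect_identical(ev$kind, "gain")
})

test_that("copy-neutral LOH is its own event kind", {
  seg <- data.frame(sample = "A", chrom = 1, start = 1, end = 10e6,
                    total_cn = 2, minor_cn = 0, clonal_fraction = 1)
  expect_identical(seg_to_events(seg)$kind, "cnloh")
  # and it never matches a loss of the same interval
  a <- seg_with_events(data.frame(chrom = 1, start = 1, end = 10e6,
                                  total_cn = 2, minor_cn = 0,
                                  clonal_fraction = 1), "A")
  b <- seg_with_events(data.frame(chrom = 1, start = 1, end = 10e6,
                                  total_cn = 1, minor_cn = 0,
                                  clonal_fraction = 1), "B")
  expect_equal(unshared_cna_count(a, b)$delta_cna, 2)
})
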