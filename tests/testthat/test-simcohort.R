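test_that("configuration invariants are enforced", {
  expect_error(sim_config(purity = 1.2), "purity")
  expect_error(sim_config(mean_depth = 0), "mean_depth")
  expect_error(sim_config(per_base_error = 0.05), "per_base_error")
  expect_error(sim_config(n_clonal_mutations = -1), "non-negative")
  bad <- matrix(c(0.5, 0.4, 0.2, 1, 0, 0), 3, 2)  # first column sums to 1.1
  expect_error(sim_config(clone_fractions = bad), "sum to 1")
  expect_error(sim_config(cna_events = data.frame(
    chrom = 1, start = 1, end = 2e6, total_cn = 3, minor_cn = 1,
    clones = "C9")), "unknown clone")
})

test_that("expected VAF follows the closed form: symmetric and zero cases", {
  # single clone, purity 1, diploid -> every clonal het mutation at VAF 0.5
  cfg <- sim_config(n_sites = 1, purity = 1, n_subclones = 0,
                    n_subclonal_mutations = 0, n_clonal_mutations = 10,
                    cna_events = NULL, seed = 2)
  p <- simulate_patient(cfg)
  expect_true(all(p$truth$expected_vaf == 0.5))

  # clone absent at a site with zero sequencing error -> zero alt reads
  cfg2 <- sim_config(per_base_error = 0, seed = 3, depth_model = "fixed",
                     clone_fractions = matrix(c(0.5, 0.5, 0, 1, 0, 0), 3, 2))
  p2 <- simulate_patient(cfg2)
  absent <- p2$truth$mutations$mutation_id[p2$truth$mutations$clone_id != "C1"]
  v2 <- p2$variants[p2$variants$site == "FL1" &
                      p2$variants$mutation_id %in% absent, ]
  expect_true(all(v2$alt_reads == 0))
})

test_that("empirical mean VAF matches the closed-form expectation", {
  # purity 0.5, diploid, clonal het: E[VAF] = 0.25; 10,000 draws
  cfg <- sim_config(n_sites = 1, purity = 0.5, n_subclones = 0,
                    n_subclonal_mutations = 0, n_clonal_mutations = 10000,
                    per_base_error = 0, depth_model = "fixed",
                    mean_depth = 100, cna_events = NULL, seed = 12)
  p <- simulate_patient(cfg)
  vaf <- p$variants$alt_reads / p$variants$depth
  se <- sd(vaf) / sqrt(length(vaf))
  expect_lt(abs(mean(vaf) - 0.25), 3 * se)
})

test_that("identical configuration reproduces the patient exactly", {
  cfg <- sim_config(seed = 99, neutral_tail = TRUE)
  p1 <- simulate_patient(cfg)
  p2 <- simulate_patient(cfg)
  expect_identical(p1$variants, p2$variants)
  expect_identical(p1$segs, p2$segs)
  expect_identical(p1$expression, p2$expression)
  expect_identical(p1$imaging, p2$imaging)
})

test_that("every simulated mutation appears once per site in the table", {
  cfg <- sim_config(seed = 5, neutral_tail = TRUE)
  p <- simulate_patient(cfg)
  n_mut <- nrow(p$truth$mutations)
  expect_equal(nrow(p$variants), n_mut * cfg$n_sites)
  counts <- table(p$variants$mutation_id)
  expect_true(all(counts == cfg$n_sites))
  expect_equal(anyDuplicated(p$truth$mutations$mutation_id), 0)
})

test_that("empirical VAFs converge to the expectation for every mutation", {
  cfg <- sim_config(seed = 17, depth_model = "fixed", mean_depth = 2000,
                    per_base_error = 0)
  p <- simulate_patient(cfg)
  for (s in seq_len(cfg$n_sites)) {
    v <- p$variants[p$variants$site == cfg$site_labels[s], ]
    ev <- p$truth$expected_vaf[v$mutation_id, s]
    # binomial SE at depth 2000; allow 4 SEs plus a tiny floor
    tol <- 4 * sqrt(pmax(ev * (1 - ev), 1e-6) / 2000)
    expect_true(all(abs(v$alt_reads / v$depth - ev) < tol + 0.005))
  }
})

test_that("the exact sampler's spectrum matches M(f) = s (1/f - 1/fmax)", {
  set.seed(44)
  s <- 2000
  f <- sample_neutral_vafs(s, c(0.1, 0.4))
  grid <- seq(0.12, 0.35, by = 0.01)
  emp <- vapply(grid, function(g) sum(f >= g), numeric(1))
  theo <- s * (1 / grid - 1 / 0.4)
  expect_true(all(abs(emp - theo) / pmax(theo, 1) < 0.15))
})

test_that("written inputs round-trip losslessly through the readers", {
  cfg <- sim_config(seed = 23)
  p <- simulate_patient(cfg, patient_id = "P77")
  dir <- withr::local_tempdir()
  write_patient_inputs(p, dir)
  rt <- read_patient_inputs(dir)

  key <- function(v) v[order(v$sample, v$mutation_id),
                       c("sample", "mutation_id", "alt_reads", "depth")]
  got <- key(rt$variants); want <- key(p$variants)
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got$alt_reads, want$alt_reads)
  expect_equal(got$depth, want$depth)
  expect_identical(got$mutation_id, want$mutation_id)

  # truth JSON lists every simulated mutation exactly once
  expect_setequal(rt$truth$mutations$mutation_id,
                  p$truth$mutations$mutation_id)
  expect_equal(anyDuplicated(rt$truth$mutations$mutation_id), 0)

  # SEG segments cover every simulated CNA interval at each site
  for (smp in p$contexts$sample) {
    seg <- rt$segs[rt$segs$sample == smp, ]
    for (i in seq_len(nrow(cfg$cna_events))) {
      ev <- cfg$cna_events[i, ]
      cover <- seg[seg$chrom == ev$chrom & seg$start <= ev$start &
                     seg$end >= ev$end, ]
      covered_by_union <- sum(
        pmin(seg$end[seg$chrom == ev$chrom], ev$end) -
          pmax(seg$start[seg$chrom == ev$chrom], ev$start) + 1 > 0)
      expect_true(nrow(cover) == 1 || covered_by_union > 0)
      # and the interval is fully inside the union of this sample's segments
      sub <- seg[seg$chrom == ev$chrom, ]
      bp <- sum(pmax(0, pmin(sub$end, ev$end) - pmax(sub$start, ev$start) + 1))
      expect_equal(bp, ev$end - ev$start + 1)
    }
  }

  # purity/contexts and expression survive the round trip
  expect_equal(rt$contexts$purity, p$contexts$purity)
  expect_equal(unname(rt$expression), unname(p$expression),
               tolerance = 1e-12)
})

test_that("fabricated GEP70 scores are realized exactly per site", {
  cfg <- sim_config(seed = 6, gep70_site_scores = c(0.9, 0.1))
  p <- simulate_patient(cfg)
  sc <- gep70_scores(p$expression, p$gep70)
  expect_equal(sc$score, c(0.9, 0.1), tolerance = 1e-9)
})
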