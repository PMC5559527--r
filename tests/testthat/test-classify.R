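test_that("variant filters: 5% VAF somewhere, coverage exceeding 20x everywhere", {
  v <- data.frame(
    patient = "P",
    sample = rep(c("S1", "S2"), each = 3),
    mutation_id = rep(c("m1", "m2", "m3"), 2),
    chrom = 1, pos = rep(c(100, 200, 300), 2),
    alt_reads = c(4, 30, 10, 0, 25, 9),
    depth = c(100, 100, 100, 100, 20, 100))
  out <- filter_variants(v)
  # m1: VAF 0.04 max -> removed; m2: depth 20 (not exceeding 20) -> removed
  expect_setequal(unique(out$mutation_id), "m3")
  fc <- attr(out, "filter_counts")
  expect_equal(fc$variants_in, 3)
  expect_equal(fc$variants_out, 1)

  # all-pass toy table is returned unchanged
  v3 <- v[v$mutation_id == "m3", ]
  out3 <- filter_variants(v3)
  expect_equal(out3[names(v3)], v3, ignore_attr = TRUE)
})

test_that("blacklisted regions (e.g. Ig loci) are excluded", {
  v <- data.frame(patient = "P", sample = c("S1", "S1"),
                  mutation_id = c("m1", "m2"), chrom = c(14, 1),
                  pos = c(106e6, 5e6), alt_reads = c(40, 40), depth = c(100, 100))
  bl <- data.frame(chrom = 14, start = 105e6, end = 107e6)
  out <- filter_variants(v, blacklist = bl)
  expect_identical(out$mutation_id, "m2")
})

test_that("detection floor arithmetic matches the 2-read rule", {
  expect_equal(min_detectable_vaf(50), 0.04)
  expect_equal(min_detectable_vaf(540), 2 / 540)
  expect_equal(min_detectable_ccf(50, purity = 1, n_locus_total = 2, n_chr = 1),
               0.08)
})

test_that("pair classification follows the published rule table", {
  th <- default_thresholds()
  # ubiquitous, 3.6-fold CCF difference -> shared_diff
  r <- classify_pair(call_row(90, 100, 0.9), call_row(25, 100, 0.25), th)
  expect_identical(r$label, "shared_diff")
  # detected vs 1 read at depth >= 50 -> unshared, subclonal at CCF 0.4
  r <- classify_pair(call_row(20, 100, 0.4), call_row(1, 120, 0.02), th)
  expect_identical(r$label, "unshared")
  expect_identical(r$clonality, "subclonal")
  # same pattern but paired depth 40 < 50 -> rescued into the totals only
  r <- classify_pair(call_row(20, 100, 0.4), call_row(1, 40, 0.05), th)
  expect_identical(r$label, "unclassified_heterogeneous")
  # ubiquitous, fold below three -> shared
  r <- classify_pair(call_row(50, 100, 0.9), call_row(40, 100, 0.35), th)
  expect_identical(r$label, "shared")
  # detected with CCF 0 on one side: infinite fold -> shared_diff when the
  # larger CCF clears the heterogeneity floor
  r <- classify_pair(call_row(30, 100, 0.5), call_row(2, 100, 0.0), th)
  expect_identical(r$label, "shared_diff")
  # negative in both -> not evaluable for this pair
  r <- classify_pair(call_row(0, 100, 0), call_row(1, 100, 0.01), th)
  expect_identical(r$label, "not_evaluable")
})

test_that("classification agrees with a brute-force rule-table oracle", {
  oracle <- function(alt_a, alt_b, depth_a, depth_b, ccf_a, ccf_b, th) {
    det <- function(x) x >= th$detect_min_reads
    neg <- function(x) x <= th$noise_max_reads
    if (det(alt_a) && neg(alt_b) || det(alt_b) && neg(alt_a)) {
      pos_ccf <- if (det(alt_a)) ccf_a else ccf_b
      neg_depth <- if (det(alt_a)) depth_b else depth_a
      if (pos_ccf >= th$het_ccf_min && neg_depth >= th$negative_min_depth) {
        return("unshared")
      }
      return("unclassified_heterogeneous")
    }
    if (det(alt_a) && det(alt_b)) {
      lo <- min(ccf_a, ccf_b); hi <- max(ccf_a, ccf_b)
      fold <- if (lo > 0) hi / lo else if (hi > 0) Inf else 1
      if (fold >= th$shared_diff_fold) {
        if (hi >= th$het_ccf_min) return("shared_diff")
        return("unclassified_heterogeneous")
      }
      return("shared")
    }
    "not_evaluable"
  }
  th <- default_thresholds()
  grid <- expand.grid(alt_a = c(0, 1, 2, 10, 40), alt_b = c(0, 1, 2, 10, 40),
                      depth = c(40, 50, 120),
                      ccf_a = c(0, 0.1, 0.2, 0.5, 0.9),
                      ccf_b = c(0, 0.19, 0.3, 0.85))
  got <- classify_pair(
    data.frame(alt_reads = grid$alt_a, depth = grid$depth, ccf = grid$ccf_a),
    data.frame(alt_reads = grid$alt_b, depth = grid$depth, ccf = grid$ccf_b),
    th)
  want <- mapply(oracle, grid$alt_a, grid$alt_b, grid$depth, grid$depth,
                 grid$ccf_a, grid$ccf_b, MoreArgs = list(th = th))
  expect_identical(got$label, unname(want))
})

test_that("raising the heterogeneity CCF floor never adds unshared calls", {
  set.seed(9)
  n <- 300
  a <- data.frame(alt_reads = sample(0:60, n, TRUE), depth = 100,
                  ccf = runif(n))
  b <- data.frame(alt_reads = sample(0:2, n, TRUE), depth = 100,
                  ccf = runif(n, 0, 0.05))
  counts <- vapply(c(0.1, 0.2, 0.3, 0.5), function(thr) {
    th <- merge_thresholds(list(het_ccf_min = thr))
    sum(classify_pair(a, b, th)$label == "unshared")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("labels partition the evaluable mutations of a simulated patient", {
  cfg <- sim_config(seed = 21, mean_depth = 200)
  p <- simulate_patient(cfg)
  calls <- suppressWarnings(
    compute_ccf(filter_variants(p$variants), p$contexts, p$segs))
  cls <- classify_patient(calls)
  labs <- cls$per_mutation$label
  expect_true(all(labs %in% c("shared", "shared_diff", "unshared",
                              "unclassified_heterogeneous", "not_evaluable")))
  s <- patient_summary(cls$per_mutation)
  expect_equal(s$n_shared + s$n_shared_diff + s$n_unshared +
                 s$n_unclassified_heterogeneous, s$n_total)
  expect_equal(s$n_unshared_clonal + s$n_unshared_subclonal, s$n_unshared)
})

test_that("without sequencing error a site-absent mutation is never shared", {
  cfg <- sim_config(seed = 31, per_base_error = 0, mean_depth = 300,
                    depth_model = "fixed",
                    clone_fractions = matrix(c(0.5, 0.5, 0, 1, 0, 0), 3, 2))
  p <- simulate_patient(cfg)
  calls <- suppressWarnings(
    compute_ccf(filter_variants(p$variants), p$contexts, p$segs))
  cls <- classify_patient(calls)
  absent <- p$truth$mutations$mutation_id[
    p$truth$mutations$clone_id %in% c("C2", "C3")]
  got <- cls$per_mutation[cls$per_mutation$mutation_id %in% absent, ]
  expect_false(any(got$label == "shared"))
})

test_that("patient summary proportions: degenerate and all-shared cases", {
  all_shared <- data.frame(mutation_id = c("m1", "m2"),
                           label = "shared", clonality = NA)
  s <- patient_summary(all_shared)
  expect_equal(s$prop_unshared, 0)
  expect_equal(s$prop_shared_diff, 0)
  none <- data.frame(mutation_id = "m1", label = "not_evaluable",
                     clonality = NA)
  s0 <- patient_summary(none)
  expect_true(is.na(s0$prop_unshared))  # undefined, not zero
})
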