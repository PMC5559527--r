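# Synthetic multi-region patient generator. A patient is a rooted clone tree
# (founder plus subclones) with site-specific clone fractions; mutations and
# CNAs are private to clones and inherited by descendants; read counts are
# drawn binomially at the configured depth under purity and locus copy
# number; expression profiles have controlled GEP70 scores; imaging rows
# couple focal-lesion size to the injected heterogeneity.

# GRCh37-scale chromosome lengths (bp), autosomes 1..22
.chrom_lengths <- c(249e6, 243e6, 198e6, 191e6, 181e6, 171e6, 159e6, 146e6,
                    141e6, 136e6, 135e6, 134e6, 115e6, 107e6, 103e6, 90e6,
                    81e6, 78e6, 59e6, 63e6, 48e6, 51e6)

#' Default CNA events for the synthetic patient
#'
#' Three canonical myeloma aberrations: a clonal deletion of 13q and a clonal
#' gain of 1q carried by the founder clone, and a del(17p) private to the
#' first subclone — the latter is the built-in source of spatial CNA
#' discordance when that subclone is regionally restricted.
#'
#' @return Data frame `chrom, start, end, total_cn, minor_cn, clones`
#'   (`clones` is a comma-separated list of carrier clone ids).
#' @export
default_cna_events <- function() {
  data.frame(
    chrom = c(13L, 1L, 17L),
    start = c(20e6, 145e6, 1),
    end   = c(110e6, 240e6, 22e6),
    total_cn = c(1L, 3L, 1L),
    minor_cn = c(0L, 1L, 0L),
    clones = c("C1", "C1", "C2"),
    stringsAsFactors = FALSE
  )
}

#' Configuration for one synthetic multi-region patient
#'
#' Defaults mirror the study design this generator emulates: two specimens
#' per patient (an iliac-crest random aspirate and a focal-lesion fine-needle
#' aspirate), CD138-enriched purity 0.9, mean whole-exome depth 129x with
#' Poisson variation, a per-base sequencing error of 1e-3 emitted as alt
#' reads, and roughly 50 non-silent mutations split between the founder clone
#' and two subclones.
#'
#' @param n_sites Number of specimens (>= 1).
#' @param site_labels Site names; defaults to `iliac_crest`, `FL1`, ...
#' @param purity Per-site tumor purity in `(0, 1]` (recycled).
#' @param mean_depth Mean sequencing depth (> 0).
#' @param depth_model `"poisson"` (default) or `"fixed"`.
#' @param per_base_error Per-base error rate in `[0, 0.01]`, emitted as alt
#'   reads on top of the binomial draw.
#' @param n_clonal_mutations Mutations private to the founder (CCF 1
#'   everywhere).
#' @param n_subclonal_mutations Mutations split evenly across the subclones.
#' @param n_subclones Number of subclones (children of the founder).
#' @param clone_fractions Optional matrix (clones x sites, rows
#'   `C1..C(1+n_subclones)`) of cell fractions, each column summing to 1.
#'   `NULL` draws them: each subclone is seeded at each site with probability
#'   `site_presence_prob`, and fractions of the seeded clones follow a
#'   Dirichlet(1) draw.
#' @param site_presence_prob Seeding probability used by the random
#'   composition draw (regional dominance: an unseeded subclone has fraction
#'   0, making its mutations truly absent at that site).
#' @param cna_events Data frame of CNA events (see [default_cna_events()]);
#'   may have zero rows.
#' @param neutral_tail If `TRUE`, add site-private neutral 1/f mutation tails.
#' @param neutral_mutation_rate Slope mu/beta of the added tails.
#' @param gep70_up_n,gep70_down_n Sizes of the fabricated signature gene sets
#'   (placeholder gene identities `UP...`/`DN...`; the real signature genes
#'   are configuration inputs throughout the package).
#' @param gep70_site_scores Target GEP70 scores per site (realized exactly);
#'   `NULL` draws them from N(0.3, 0.4).
#' @param fl_link If `TRUE`, maximum focal-lesion diameter increases with the
#'   injected unshared-mutation fraction; otherwise it is independent.
#' @param seed Integer seed; the full patient is a deterministic function of
#'   the configuration.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_sites = 2L,
                       site_labels = NULL,
                       purity = 0.9,
                       mean_depth = 129,
                       depth_model = c("poisson", "fixed"),
                       per_base_error = 0.001,
                       n_clonal_mutations = 25L,
                       n_subclonal_mutations = 25L,
                       n_subclones = 2L,
                       clone_fractions = NULL,
                       site_presence_prob = 0.6,
                       cna_events = default_cna_events(),
                       neutral_tail = FALSE,
                       neutral_mutation_rate = 20,
                       gep70_up_n = 51L,
                       gep70_down_n = 19L,
                       gep70_site_scores = NULL,
                       fl_link = TRUE,
                       seed = 1L) {
  depth_model <- match.arg(depth_model)
  n_sites <- as.integer(n_sites)
  if (n_sites < 1L) stop("n_sites must be >= 1")
  if (is.null(site_labels)) {
    site_labels <- c("iliac_crest",
                     if (n_sites > 1L) paste0("FL", seq_len(n_sites - 1L)))
  }
  stopifnot(length(site_labels) == n_sites)
  purity <- rep_len(purity, n_sites)
  if (any(purity <= 0 | purity > 1)) stop("purity must lie in (0, 1]")
  if (mean_depth <= 0) stop("mean_depth must be > 0")
  if (per_base_error < 0 || per_base_error > 0.01) {
    stop("per_base_error must lie in [0, 0.01]")
  }
  if (n_clonal_mutations < 0 || n_subclonal_mutations < 0 || n_subclones < 0) {
    stop("mutation and clone counts must be non-negative")
  }
  n_clones <- 1L + as.integer(n_subclones)
  clone_ids <- paste0("C", seq_len(n_clones))
  if (!is.null(clone_fractions)) {
    clone_fractions <- as.matrix(clone_fractions)
    if (nrow(clone_fractions) != n_clones || ncol(clone_fractions) != n_sites) {
      stop("clone_fractions must be ", n_clones, " clones x ", n_sites, " sites")
    }
    if (any(abs(colSums(clone_fractions) - 1) > 1e-9)) {
      stop("clone_fractions columns must sum to 1")
    }
    if (any(clone_fractions < 0)) stop("clone fractions must be non-negative")
    rownames(clone_fractions) <- clone_ids
  }
  if (!is.null(cna_events) && nrow(cna_events) > 0L) {
    stopifnot(all(c("chrom", "start", "end", "total_cn", "minor_cn", "clones")
                  %in% names(cna_events)))
    carriers <- unlist(strsplit(cna_events$clones, ","))
    if (!all(carriers %in% clone_ids)) {
      stop("cna_events references unknown clone(s): ",
           paste(setdiff(carriers, clone_ids), collapse = ", "))
    }
  }
  structure(list(
    n_sites = n_sites, site_labels = site_labels, purity = purity,
    mean_depth = mean_depth, depth_model = depth_model,
    per_base_error = per_base_error,
    n_clonal_mutations = as.integer(n_clonal_mutations),
    n_subclonal_mutations = as.integer(n_subclonal_mutations),
    n_subclones = as.integer(n_subclones), clone_ids = clone_ids,
    clone_fractions = clone_fractions,
    site_presence_prob = site_presence_prob,
    cna_events = cna_events,
    neutral_tail = isTRUE(neutral_tail),
    neutral_mutation_rate = neutral_mutation_rate,
    gep70_up_n = as.integer(gep70_up_n),
    gep70_down_n = as.integer(gep70_down_n),
    gep70_site_scores = gep70_site_scores,
    fl_link = isTRUE(fl_link),
    seed = as.integer(seed)
  ), class = "sim_config")
}

# random genomic positions avoiding the configured CNA intervals (so SNV loci
# are diploid in every sample and the closed-form expected VAF is exact)
.draw_positions <- function(n, cna_events) {
  chrom <- integer(n); pos <- numeric(n)
  i <- 1L
  while (i <= n) {
    ch <- sample.int(22L, 1L)
    p <- ceiling(runif(1, 1, .chrom_lengths[ch]))
    inside <- FALSE
    if (!is.null(cna_events) && nrow(cna_events) > 0L) {
      inside <- any(cna_events$chrom == ch &
                      cna_events$start <= p & cna_events$end >= p)
    }
    if (!inside) {
      chrom[i] <- ch; pos[i] <- p; i <- i + 1L
    }
  }
  list(chrom = chrom, pos = pos)
}

#' Simulate one multi-region patient
#'
#' Draws the clone tree, site compositions, mutations, CNAs, read counts,
#' expression and imaging for one patient and returns both the ground truth
#' and the pipeline-ready input tables. For every mutation `m` and site `s`
#' the expected VAF is
#' `CCF_ms * n_chr * p_s / (p_s * n_locus + 2 (1 - p_s))`
#' with `CCF_ms` the summed fraction of clones carrying `m` at `s`; alt reads
#' are binomial at the realized depth plus error reads at `per_base_error`.
#' The same configuration (including seed) reproduces the patient exactly.
#'
#' @param config A [sim_config()].
#' @param patient_id Identifier used in the output tables.
#' @return Object of class `sim_patient`: list with `truth` (tree, site
#'   compositions, mutation map, true CCF and expected-VAF matrices, CNAs,
#'   injected unshared fraction), `variants` (long read-count table),
#'   `contexts`, `segs`, `expression`, `gep70` (the fabricated
#'   [gep70_config()]), `imaging`, `clinical` and `config`.
#' @export
simulate_patient <- function(config, patient_id = "P01") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ns <- config$n_sites
  sites <- config$site_labels
  samples <- paste0(patient_id, "_", sites)
  clone_ids <- config$clone_ids
  n_clones <- length(clone_ids)

  tree <- data.frame(clone_id = clone_ids,
                     parent_id = c("root", rep(clone_ids[1L], n_clones - 1L)),
                     stringsAsFactors = FALSE)

  # site compositions ------------------------------------------------------
  frac <- config$clone_fractions
  if (is.null(frac)) {
    frac <- matrix(0, n_clones, ns, dimnames = list(clone_ids, sites))
    for (s in seq_len(ns)) {
      present <- c(TRUE, runif(n_clones - 1L) < config$site_presence_prob)
      w <- ifelse(present, rgamma(n_clones, 1), 0)
      frac[, s] <- w / sum(w)
    }
  } else {
    colnames(frac) <- sites
  }

  # mutations --------------------------------------------------------------
  n_sub <- config$n_subclones
  clone_of <- c(rep(clone_ids[1L], config$n_clonal_mutations),
                if (config$n_subclonal_mutations > 0L && n_sub > 0L) {
                  clone_ids[1L + (seq_len(config$n_subclonal_mutations) - 1L) %%
                              n_sub + 1L]
                })
  n_core <- length(clone_of)
  loc <- .draw_positions(n_core, config$cna_events)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_core, replace = TRUE)
  alt_allele <- vapply(ref, function(r) sample(setdiff(bases, r), 1L),
                       character(1))
  mutations <- data.frame(
    mutation_id = sprintf("m%04d", seq_len(n_core)),
    chrom = loc$chrom, pos = loc$pos, ref = ref, alt_allele = alt_allele,
    clone_id = clone_of, type = "core", stringsAsFactors = FALSE)

  # carriers: a clone carries its own and all ancestral mutations; in the
  # star tree the founder's mutations are carried by everyone
  carrier <- matrix(FALSE, n_core, n_clones, dimnames = list(NULL, clone_ids))
  carrier[, 1L] <- clone_of == clone_ids[1L]
  for (k in seq_len(n_clones - 1L)) {
    carrier[, k + 1L] <- clone_of == clone_ids[1L] | clone_of == clone_ids[k + 1L]
  }
  ccf_true <- carrier %*% frac                       # mutations x sites
  dimnames(ccf_true) <- list(mutations$mutation_id, sites)

  # neutral tails: site-private subclonal 1/f spectra
  if (config$neutral_tail) {
    for (s in seq_len(ns)) {
      f_tail <- sample_neutral_vafs(config$neutral_mutation_rate,
                                    c(0.05, 0.5))
      if (length(f_tail) == 0L) next
      nt <- length(f_tail)
      tl <- .draw_positions(nt, config$cna_events)
      t_ref <- sample(bases, nt, replace = TRUE)
      t_alt <- vapply(t_ref, function(r) sample(setdiff(bases, r), 1L),
                      character(1))
      t_ids <- sprintf("t%s_%04d", sites[s], seq_len(nt))
      mutations <- rbind(mutations, data.frame(
        mutation_id = t_ids, chrom = tl$chrom, pos = tl$pos,
        ref = t_ref, alt_allele = t_alt, clone_id = NA_character_,
        type = "neutral_tail", stringsAsFactors = FALSE))
      # tail VAFs are drawn directly on the VAF scale of a pure diploid
      # sample; convert back to cell-fraction CCF (f = ccf * p / 2 at p = 1)
      add <- matrix(0, nt, ns)
      add[, s] <- pmin(1, 2 * f_tail)
      ccf_true <- rbind(ccf_true, add)
    }
    dimnames(ccf_true) <- list(mutations$mutation_id, sites)
  }

  n_mut <- nrow(mutations)
  exp_vaf <- sapply(seq_len(ns), function(s) {
    expected_vaf(ccf_true[, s], n_chr = 1, purity = config$purity[s],
                 n_locus_total = 2)
  })
  exp_vaf <- matrix(exp_vaf, nrow = n_mut,
                    dimnames = list(mutations$mutation_id, sites))

  # read counts ------------------------------------------------------------
  variants <- do.call(rbind, lapply(seq_len(ns), function(s) {
    d <- if (config$depth_model == "fixed") {
      rep(round(config$mean_depth), n_mut)
    } else {
      pmax(1L, rpois(n_mut, config$mean_depth))
    }
    alt <- rbinom(n_mut, d, exp_vaf[, s])
    if (config$per_base_error > 0) {
      alt <- pmin(d, alt + rbinom(n_mut, d, config$per_base_error))
    }
    data.frame(patient = patient_id, sample = samples[s], site = sites[s],
               mutation_id = mutations$mutation_id,
               chrom = mutations$chrom, pos = mutations$pos,
               ref = mutations$ref, alt_allele = mutations$alt_allele,
               alt_reads = alt, depth = d, stringsAsFactors = FALSE)
  }))
  rownames(variants) <- NULL

  contexts <- data.frame(sample = samples, site = sites,
                         purity = config$purity,
                         mean_depth = config$mean_depth,
                         stringsAsFactors = FALSE)

  # segmented copy-number profiles -----------------------------------------
  segs <- do.call(rbind, lapply(seq_len(ns), function(s) {
    build_seg_profile(config$cna_events, frac[, s], samples[s])
  }))

  # expression with controlled GEP70 scores --------------------------------
  up <- sprintf("UP%03d", seq_len(config$gep70_up_n))
  dn <- sprintf("DN%03d", seq_len(config$gep70_down_n))
  bg <- sprintf("BG%03d", seq_len(30L))
  genes <- c(up, dn, bg)
  target <- config$gep70_site_scores
  if (is.null(target)) target <- rnorm(ns, 0.3, 0.4)
  target <- rep_len(target, ns)
  base <- rnorm(length(genes), 5, 0.5)
  expr <- sapply(seq_len(ns), function(s) base + rnorm(length(genes), 0, 0.2))
  expr <- matrix(expr, nrow = length(genes), dimnames = list(genes, samples))
  for (s in seq_len(ns)) {
    realized <- mean(expr[up, s]) - mean(expr[dn, s])
    expr[up, s] <- expr[up, s] + (target[s] - realized)
  }
  gep70 <- suppressWarnings(gep70_config(up, dn))

  # imaging ----------------------------------------------------------------
  core <- mutations$type == "core"
  prop_unshared_true <- if (ns >= 2L && sum(core) > 0L) {
    mean(apply(ccf_true[core, , drop = FALSE], 1L, function(cc) {
      min(cc) == 0 && max(cc) >= 0.2
    }))
  } else {
    0
  }
  n_fl <- rpois(1L, 18)
  max_fl <- if (config$fl_link) {
    max(0.3, round(0.8 + 5 * prop_unshared_true + rnorm(1, 0, 0.3), 1))
  } else {
    round(runif(1, 0.5, 4), 1)
  }
  imaging <- data.frame(patient_id = patient_id, n_focal_lesions = n_fl,
                        max_fl_diameter_cm = max_fl, stringsAsFactors = FALSE)

  # survival (used by the cohort survival demo): high-risk anywhere shortens
  # follow-up; ~30% censoring
  any_high <- any(target >= 0.66)
  surv_time <- round(rexp(1, rate = if (any_high) 0.35 else 0.12), 2)
  clinical <- data.frame(patient_id = patient_id,
                         survival_time = max(surv_time, 0.05),
                         event = rbinom(1L, 1L, 0.7),
                         stringsAsFactors = FALSE)

  structure(list(
    truth = list(tree = tree,
                 site_compositions = frac,
                 mutations = mutations,
                 ccf_true = ccf_true,
                 expected_vaf = exp_vaf,
                 cna_events = config$cna_events,
                 gep70_scores = setNames(target, samples),
                 prop_unshared_true = prop_unshared_true),
    variants = variants, contexts = contexts, segs = segs,
    expression = expr, gep70 = gep70, imaging = imaging,
    clinical = clinical, config = config, patient_id = patient_id
  ), class = "sim_patient")
}

#' Build a SEG-style profile from CNA events and clone fractions
#'
#' Lays the carried events over a diploid baseline covering all 22 autosomes;
#' each event row reports the event copy number and its clonal fraction at
#' the site (the summed fraction of carrier clones).
#'
#' @param cna_events Event table (see [default_cna_events()]); `NULL` or zero
#'   rows give a purely diploid profile.
#' @param clone_frac Named vector clone id -> cell fraction at this site.
#' @param sample Sample name for the output rows.
#' @return SEG data frame `sample, chrom, start, end, total_cn, minor_cn,
#'   clonal_fraction`.
#' @export
build_seg_profile <- function(cna_events, clone_frac, sample) {
  rows <- list()
  for (ch in seq_along(.chrom_lengths)) {
    len <- .chrom_lengths[ch]
    ev <- if (!is.null(cna_events) && nrow(cna_events) > 0L) {
      cna_events[cna_events$chrom == ch, , drop = FALSE]
    } else {
      NULL
    }
    ev <- if (!is.null(ev) && nrow(ev) > 0L) ev[order(ev$start), ] else NULL
    cursor <- 1
    if (!is.null(ev)) {
      for (i in seq_len(nrow(ev))) {
        carriers <- strsplit(ev$clones[i], ",")[[1L]]
        cf <- sum(clone_frac[carriers])
        if (cf <= 0) next  # event absent at this site: baseline persists
        if (ev$start[i] > cursor) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample = sample, chrom = ch, start = cursor, end = ev$start[i] - 1,
            total_cn = 2, minor_cn = 1, clonal_fraction = 1)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          sample = sample, chrom = ch, start = ev$start[i], end = ev$end[i],
          total_cn = ev$total_cn[i], minor_cn = ev$minor_cn[i],
          clonal_fraction = cf)
        cursor <- ev$end[i] + 1
      }
    }
    if (cursor <= len) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sample, chrom = ch, start = cursor, end = len,
        total_cn = 2, minor_cn = 1, clonal_fraction = 1)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a cohort of multi-region patients
#'
#' Each patient reuses the base configuration with its own derived seed and a
#' fresh random site composition, so the injected unshared fraction varies
#' across the cohort; with `fl_link` on (the default) the maximum
#' focal-lesion diameter tracks that fraction, giving the cohort-level
#' size-vs-heterogeneity association something real to recover.
#'
#' @param n_patients Number of patients.
#' @param base A [sim_config()] used as template.
#' @param seed Cohort seed; patient `i` runs at `seed * 1000 + i` (kept below
#'   `.Machine$integer.max`).
#' @return List of `sim_patient` objects, names `P01, P02, ...`
#' @export
simulate_cohort <- function(n_patients, base = sim_config(), seed = 1L) {
  stopifnot(n_patients >= 1)
  lapply(seq_len(n_patients), function(i) {
    cfg <- base
    cfg$seed <- as.integer((seed * 1000L + i) %% .Machine$integer.max)
    cfg$clone_fractions <- NULL  # fresh regional composition per patient
    cfg$gep70_site_scores <- NULL
    simulate_patient(cfg, patient_id = sprintf("P%02d", i))
  })
}
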