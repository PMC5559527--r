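# End-to-end orchestration: simulate (or load) -> CCF -> classification ->
# CNA discordance -> neutral-evolution test -> GEP70 -> cohort statistics.
# Every stage logs records in / records out; the run summary carries the
# counts, package versions and a hash of the configuration, and is
# byte-identical across reruns with the same seed.

#' Validate a pipeline run configuration
#'
#' A run configuration is a list (or a YAML file) with fields:
#' * `seed` — integer, drives every random draw;
#' * `out_dir` — output directory;
#' * `thresholds` — optional overrides of [default_thresholds()]; every known
#'   threshold must resolve to a value;
#' * exactly one of `simulate` (list: `n_patients` plus any [sim_config()]
#'   arguments) or `input_dirs` (character vector of directories readable by
#'   [read_patient_inputs()]).
#'
#' @param config List or path to a YAML file.
#' @return The validated configuration with thresholds fully merged.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  for (field in c("seed", "out_dir")) {
    if (is.null(config[[field]])) {
      stop("run configuration is missing required field: ", field)
    }
  }
  has_sim <- !is.null(config$simulate)
  has_inp <- !is.null(config$input_dirs)
  if (has_sim == has_inp) {
    stop("run configuration needs exactly one of: simulate, input_dirs")
  }
  if (has_sim && is.null(config$simulate$n_patients)) {
    stop("run configuration is missing required field: simulate$n_patients")
  }
  config$thresholds <- merge_thresholds(config$thresholds,
                                        require_complete = TRUE)
  config$seed <- as.integer(config$seed)
  config
}

#' Run the full multi-region heterogeneity pipeline
#'
#' @param config Run configuration (list or YAML path), see
#'   [validate_run_config()].
#' @param quiet Suppress per-stage log lines.
#' @return Result bundle (invisibly): per-patient call, classification and
#'   summary tables, CNA discordance, neutral-fit, GEP70 and cohort tables,
#'   the association statistics, and the run `summary` — all also written
#'   under `out_dir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  config <- validate_run_config(config)
  th <- config$thresholds
  log_line <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  # ---- stage: acquire patients -------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    n_patients <- sim_args$n_patients
    sim_args$n_patients <- NULL
    base <- do.call(sim_config, c(sim_args, list(seed = config$seed)))
    patients <- simulate_cohort(n_patients, base = base, seed = config$seed)
    patients <- lapply(patients, function(p) {
      c(unclass(p), list(truth_available = TRUE))
    })
    log_line("simulate", "generated %d patient(s)", length(patients))
  } else {
    patients <- lapply(config$input_dirs, read_patient_inputs)
    log_line("load", "read %d patient director(ies)", length(patients))
  }

  stage_counts <- list()
  per_patient <- list()

  for (p in patients) {
    pid <- if (!is.null(p$patient_id)) p$patient_id else p$imaging$patient_id[1]

    # ---- filter ----------------------------------------------------------
    filtered <- filter_variants(p$variants, blacklist = NULL, thresholds = th)
    fc <- attr(filtered, "filter_counts")
    log_line("filter", "%s: %d -> %d variants (low depth %d, low VAF %d)",
             pid, fc$variants_in, fc$variants_out,
             fc$dropped_low_depth, fc$dropped_low_vaf)

    # ---- CCF -------------------------------------------------------------
    calls <- suppressWarnings(
      compute_ccf(filtered, p$contexts, p$segs, thresholds = th))
    log_line("ccf", "%s: %d call rows", pid, nrow(calls))

    # ---- classification --------------------------------------------------
    cls <- classify_patient(calls, thresholds = th)
    summ <- patient_summary(cls$per_mutation, patient = pid)
    log_line("classify", "%s: %d evaluable, %d unshared, %d shared-diff",
             pid, summ$n_total, summ$n_unshared, summ$n_shared_diff)

    # ---- CNA discordance (mean over sample pairs) ------------------------
    samples <- p$contexts$sample
    delta <- NA_real_
    if (length(samples) >= 2L) {
      pair_counts <- c()
      for (i in seq_len(length(samples) - 1L)) {
        for (j in seq(i + 1L, length(samples))) {
          seg_a <- p$segs[p$segs$sample == samples[i], , drop = FALSE]
          seg_b <- p$segs[p$segs$sample == samples[j], , drop = FALSE]
          pair_counts <- c(pair_counts,
                           unshared_cna_count(seg_a, seg_b,
                                              size_min = th$cna_size_min,
                                              clonal_min = th$cna_clonal_min,
                                              overlap_min = th$cna_overlap_min)$delta_cna)
        }
      }
      delta <- mean(pair_counts)
    }
    log_line("cna-diff", "%s: delta CNA %.1f", pid, delta)

    # ---- neutral-evolution test ------------------------------------------
    neutral <- neutral_fit_samples(calls, thresholds = th)
    log_line("neutral", "%s: %d/%d sample(s) eligible", pid,
             sum(neutral$eligible), nrow(neutral))

    # ---- GEP70 -----------------------------------------------------------
    gep <- NULL
    discord <- NA_character_
    if (!is.null(p$expression) && !is.null(p$gep70)) {
      gep <- gep70_scores(p$expression, p$gep70)
      gep$patient <- pid
      discord <- risk_discordance(gep$score,
                                  threshold = th$gep70_threshold)
      log_line("gep70", "%s: scores %s -> %s", pid,
               paste(sprintf("%.2f", gep$score), collapse = "/"), discord)
    }

    stage_counts[[pid]] <- list(
      variants_in = fc$variants_in, variants_filtered_out =
        fc$variants_in - fc$variants_out,
      variants_analyzed = fc$variants_out,
      evaluable = summ$n_total,
      not_evaluable = length(unique(calls$mutation_id)) - summ$n_total)

    per_patient[[pid]] <- list(
      calls = calls, classification = cls, summary = summ,
      delta_cna = delta, neutral = neutral, gep70 = gep,
      discordance = discord, imaging = p$imaging, clinical = p$clinical)
  }

  # ---- cohort assembly ----------------------------------------------------
  cohort <- do.call(rbind, lapply(per_patient, function(pp) {
    row <- pp$summary
    row$delta_cna <- pp$delta_cna
    row$max_fl_cm <- pp$imaging$max_fl_diameter_cm[1]
    row$n_fl <- pp$imaging$n_focal_lesions[1]
    row$risk_discordance <- pp$discordance
    row$survival_time <- if (!is.null(pp$clinical)) {
      pp$clinical$survival_time[1]
    } else {
      NA_real_
    }
    row$event <- if (!is.null(pp$clinical)) pp$clinical$event[1] else NA
    row
  }))
  rownames(cohort) <- NULL

  # ---- cohort statistics --------------------------------------------------
  stats_report <- NULL
  if (nrow(cohort) >= 5L) {
    stats_report <- cohort_associations(cohort)
    km <- NULL
    lr <- NULL
    surv_ok <- !is.na(cohort$survival_time) & cohort$survival_time > 0
    groups <- cohort$risk_discordance
    if (sum(surv_ok) >= 5L && length(unique(groups[surv_ok])) >= 2L) {
      km <- kaplan_meier(cohort$survival_time[surv_ok],
                         cohort$event[surv_ok])
      lr <- log_rank(cohort$survival_time[surv_ok], cohort$event[surv_ok],
                     groups[surv_ok])
    }
    stats_report$km <- km
    stats_report$log_rank <- lr
    log_line("stats", "cohort n=%d; %s", nrow(cohort),
             if (!is.null(stats_report$correlations)) {
               sprintf("max-FL vs unshared rho=%.2f",
                       stats_report$correlations$rho[
                         stats_report$correlations$outcome == "prop_unshared" &
                         stats_report$correlations$predictor == "max_fl_cm"][1])
             } else "no correlations computed")
  }

  # ---- outputs ------------------------------------------------------------
  all_calls <- do.call(rbind, lapply(per_patient, function(pp) pp$calls))
  all_cls <- do.call(rbind, lapply(names(per_patient), function(pid) {
    cbind(patient = pid, per_patient[[pid]]$classification$per_mutation)
  }))
  write.csv(all_calls, file.path(config$out_dir, "calls.csv"),
            row.names = FALSE)
  write.csv(all_cls, file.path(config$out_dir, "classification.csv"),
            row.names = FALSE)
  write.csv(cohort, file.path(config$out_dir, "cohort.csv"),
            row.names = FALSE)
  neutral_all <- do.call(rbind, lapply(per_patient, function(pp) pp$neutral))
  write.csv(neutral_all, file.path(config$out_dir, "neutral.csv"),
            row.names = FALSE)

  summary <- list(
    package = "spatialmm",
    package_version = as.character(packageVersion("spatialmm")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = config_hash(config),
    n_patients = length(per_patient),
    thresholds = th,
    stage_counts = stage_counts
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(per_patient = per_patient, cohort = cohort,
                 stats = stats_report, summary = summary,
                 out_dir = config$out_dir))
}

#' Hash a run configuration
#'
#' MD5 of the canonical JSON serialization (out_dir excluded, so the same
#' analysis written to different places hashes identically).
#'
#' @param config Validated run configuration.
#' @return Hex digest string.
#' @export
config_hash <- function(config) {
  config$out_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}
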