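# Neutral-evolution test: under neutral tumor growth the cumulative number of
# subclonal mutations with VAF >= f grows linearly in 1/f,
#   M(f) = (mu/beta) * (1/f - 1/f_max),
# where mu/beta is the mutation rate per effective cell division. A sample is
# called neutral when a zero-intercept least-squares fit of M(f) against
# (1/f - 1/f_max) over the subclonal VAF window explains the spectrum with
# R^2 >= 0.98.

#' Cumulative mutation-frequency spectrum M(f)
#'
#' For each distinct VAF `f` (sorted descending), `M(f)` is the number of
#' mutations with VAF at least `f`. The x-coordinate of each support point is
#' `1/f - 1/f_max`. Duplicate VAFs collapse to one support point with the
#' correct cumulative count (step height > 1 allowed). Output is invariant to
#' input order.
#'
#' @param vafs Numeric vector of VAFs in `(0, 1)`.
#' @param window Optional `(lo, hi)` pair: only VAFs strictly inside the
#'   window are used. `NULL` (default) keeps all.
#' @param f_max Frequency at which `1/f - 1/f_max` vanishes; defaults to the
#'   window upper bound, or the largest retained VAF when no window is given.
#' @return Data frame with columns `f`, `x` (`= 1/f - 1/f_max`) and `M`,
#'   ordered by decreasing `f`. Zero rows when nothing falls in the window.
#' @examples
#' cumulative_spectrum(c(0.24, 0.18, 0.13))  # M = 1, 2, 3
#' @export
cumulative_spectrum <- function(vafs, window = NULL, f_max = NULL) {
  stopifnot(is.numeric(vafs))
  vafs <- vafs[!is.na(vafs)]
  if (any(vafs <= 0 | vafs >= 1)) stop("vafs must lie strictly in (0, 1)")
  if (!is.null(window)) {
    stopifnot(length(window) == 2L, window[1] < window[2])
    vafs <- vafs[vafs > window[1] & vafs < window[2]]
    if (is.null(f_max)) f_max <- window[2]
  }
  if (length(vafs) == 0L) {
    return(data.frame(f = numeric(0), x = numeric(0), M = numeric(0)))
  }
  if (is.null(f_max)) f_max <- max(vafs)
  f <- sort(unique(vafs), decreasing = TRUE)
  M <- vapply(f, function(fi) sum(vafs >= fi), numeric(1))
  data.frame(f = f, x = 1 / f - 1 / f_max, M = M)
}

#' Fit the neutral-growth model to one sample's VAF spectrum
#'
#' Applies the eligibility rule (at least `min_snvs` SNVs with VAF strictly
#' inside `window`), builds the cumulative spectrum, and fits
#' `M(f) = slope * (1/f - 1/f_max)` by zero-intercept ordinary least squares.
#' The model has no intercept term, so the fitted slope estimates mu/beta, the
#' mutation rate per effective cell division. R-squared is computed against
#' the mean of `M` (`1 - SS_res / SS_tot`, clamped below at 0) — stated
#' explicitly because zero-intercept R-squared conventions differ.
#'
#' @param vafs Numeric vector of VAFs for one sample (all mutations; the
#'   window is applied here).
#' @param min_snvs Eligibility floor (default 12 in-window SNVs).
#' @param window Exclusive VAF window, default `(0.12, 0.24)`.
#' @param r2_threshold Verdict threshold, default 0.98.
#' @param f_max Defaults to the window upper bound.
#' @return Object of class `neutral_fit`: list with `n_in_window`, `eligible`,
#'   `slope`, `r_squared`, `verdict` (`"neutral"`, `"non_neutral"` or
#'   `"not_evaluable"`), and the `spectrum` data frame.
#' @export
fit_neutral <- function(vafs,
                        min_snvs = 12L,
                        window = c(0.12, 0.24),
                        r2_threshold = 0.98,
                        f_max = window[2]) {
  stopifnot(length(window) == 2L, window[1] < window[2], min_snvs >= 1)
  vafs <- vafs[!is.na(vafs)]
  inw <- vafs[vafs > window[1] & vafs < window[2]]
  n_in <- length(inw)
  res <- list(n_in_window = n_in,
              eligible = n_in >= min_snvs,
              slope = NA_real_, r_squared = NA_real_,
              verdict = "not_evaluable",
              spectrum = NULL,
              window = window, f_max = f_max,
              min_snvs = min_snvs, r2_threshold = r2_threshold)
  class(res) <- "neutral_fit"
  if (!res$eligible) return(res)

  sp <- cumulative_spectrum(inw, window = window, f_max = f_max)
  slope <- sum(sp$x * sp$M) / sum(sp$x^2)
  ss_res <- sum((sp$M - slope * sp$x)^2)
  ss_tot <- sum((sp$M - mean(sp$M))^2)
  r2 <- if (ss_tot == 0) {
    if (ss_res == 0) 1 else 0  # degenerate single-support-point spectrum
  } else {
    max(0, 1 - ss_res / ss_tot)
  }
  res$slope <- slope
  res$r_squared <- r2
  res$spectrum <- sp
  res$verdict <- if (r2 >= r2_threshold) "neutral" else "non_neutral"
  res
}

#' @export
print.neutral_fit <- function(x, ...) {
  cat("Neutral-evolution fit\n")
  cat(sprintf("  in-window SNVs : %d (window %.2f-%.2f exclusive, need >= %d)\n",
              x$n_in_window, x$window[1], x$window[2], x$min_snvs))
  if (x$verdict == "not_evaluable") {
    cat("  verdict        : not evaluable\n")
  } else {
    cat(sprintf("  slope (mu/beta): %.3f\n", x$slope))
    cat(sprintf("  R-squared      : %.4f (threshold %.2f)\n",
                x$r_squared, x$r2_threshold))
    cat(sprintf("  verdict        : %s\n", x$verdict))
  }
  invisible(x)
}

#' Neutral-evolution test across samples of a call table
#'
#' @param calls Long variant table with columns `sample, alt_reads, depth`
#'   (VAF is recomputed as `alt_reads / depth`).
#' @param thresholds Threshold list, see [default_thresholds()].
#' @return One-row-per-sample data frame: `sample, n_in_window, eligible,
#'   slope, r_squared, verdict`.
#' @export
neutral_fit_samples <- function(calls, thresholds = default_thresholds()) {
  th <- merge_thresholds(thresholds)
  samples <- unique(calls$sample)
  rows <- lapply(samples, function(s) {
    sub <- calls[calls$sample == s & calls$depth > 0, , drop = FALSE]
    fit <- fit_neutral(sub$alt_reads / sub$depth,
                       min_snvs = th$neutral_min_snvs,
                       window = th$neutral_window,
                       r2_threshold = th$neutral_r2)
    data.frame(sample = s, n_in_window = fit$n_in_window,
               eligible = fit$eligible, slope = fit$slope,
               r_squared = fit$r_squared, verdict = fit$verdict,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
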