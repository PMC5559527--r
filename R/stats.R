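# Cohort-level association statistics. Standard tests are delegated to the
# stats and survival packages; the recursive partitioning of heterogeneity by
# focal-lesion size is implemented here as an exhaustive Wilcoxon midpoint
# search with Bonferroni correction over candidate cutpoints.

#' Spearman rank correlation
#'
#' Rank correlation with midrank ties; the p-value comes from
#' [stats::cor.test()] (exact for small tie-free samples, asymptotic
#' otherwise). Constant input yields an undefined (`NA`) coefficient with a
#' flag — never a silent 0.
#'
#' @param x,y Paired numeric vectors; pairs with missing values are dropped;
#'   at least 3 complete pairs required.
#' @return List `rho`, `p_value`, `n`, `defined`.
#' @export
spearman_assoc <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    return(list(rho = NA_real_, p_value = NA_real_, n = length(x),
                defined = FALSE))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       defined = TRUE)
}

#' Two-sided Mann-Whitney Wilcoxon rank-sum test
#'
#' Thin wrapper over [stats::wilcox.test()]: exact p for small tie-free
#' samples, normal approximation with tie correction otherwise. The statistic
#' is the Mann-Whitney U for the first group.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @param exact Passed through to `wilcox.test` (default: let it decide).
#' @return List `statistic` (U), `p_value`.
#' @export
wilcoxon_rank_sum <- function(group_a, group_b, exact = NULL) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be non-empty")
  }
  wt <- suppressWarnings(wilcox.test(group_a, group_b, exact = exact,
                                     alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Bonferroni-Holm step-down adjustment
#'
#' @param pvalues Numeric vector of raw p-values in `[0, 1]`.
#' @param alpha Family-wise error level for the decisions (default 0.05,
#'   two-sided).
#' @return Data frame `p_raw, p_adjusted, significant` in input order.
#' @export
holm_correction <- function(pvalues, alpha = 0.05) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  adj <- p.adjust(pvalues, method = "holm")
  data.frame(p_raw = pvalues, p_adjusted = adj,
             significant = !is.na(adj) & adj < alpha)
}

#' Recursive partitioning of a response by one continuous predictor
#'
#' Binary recursive splitting: at each node every midpoint between consecutive
#' distinct predictor values (leaving at least `min_node` observations on each
#' side) is scored by the two-sided Wilcoxon rank-sum p-value between the
#' resulting groups; the best cutpoint is accepted only if its
#' Bonferroni-adjusted p (over the node's candidate cutpoints) is below
#' `alpha`. Recursion continues on both children until no acceptable split
#' remains. A constant predictor produces no split.
#'
#' @param predictor,response Numeric vectors of equal length.
#' @param alpha Split acceptance level (default 0.05).
#' @param min_node Minimum observations per resulting group (default 5).
#' @return Object of class `recursive_partition`: list with `cutpoints`
#'   (sorted numeric vector), `groups` (integer leaf assignment, ordered along
#'   the predictor), and `leaves` (per-leaf n and median response).
#' @export
recursive_partition <- function(predictor, response, alpha = 0.05,
                                min_node = 5L) {
  stopifnot(length(predictor) == length(response), min_node >= 1)
  ok <- is.finite(predictor) & is.finite(response)
  x <- predictor[ok]; y <- response[ok]

  split_node <- function(idx) {
    if (length(idx) < 2L * min_node) return(numeric(0))
    xs <- x[idx]; ys <- y[idx]
    ux <- sort(unique(xs))
    if (length(ux) < 2L) return(numeric(0))
    cand <- (ux[-length(ux)] + ux[-1L]) / 2
    cand <- cand[vapply(cand, function(ct) {
      sum(xs <= ct) >= min_node && sum(xs > ct) >= min_node
    }, logical(1))]
    if (length(cand) == 0L) return(numeric(0))
    pv <- vapply(cand, function(ct) {
      suppressWarnings(wilcox.test(ys[xs <= ct], ys[xs > ct],
                                   exact = FALSE)$p.value)
    }, numeric(1))
    if (all(is.na(pv))) return(numeric(0))
    best <- which.min(pv)
    if (min(pmin(pv[best] * length(cand), 1), na.rm = TRUE) >= alpha) {
      return(numeric(0))
    }
    ct <- cand[best]
    c(split_node(idx[x[idx] <= ct]), ct, split_node(idx[x[idx] > ct]))
  }

  cuts <- sort(split_node(seq_along(x)))
  groups <- findInterval(x, cuts) + 1L
  leaves <- if (length(x) > 0L) {
    do.call(rbind, lapply(sort(unique(groups)), function(g) {
      data.frame(group = g, n = sum(groups == g),
                 median_response = median(y[groups == g]))
    }))
  } else {
    data.frame(group = integer(0), n = integer(0),
               median_response = numeric(0))
  }
  structure(list(cutpoints = cuts, groups = groups, leaves = leaves,
                 alpha = alpha, min_node = min_node),
            class = "recursive_partition")
}

#' @export
print.recursive_partition <- function(x, ...) {
  if (length(x$cutpoints) == 0L) {
    cat("Recursive partition: no split (single group)\n")
  } else {
    cat("Recursive partition: cutpoints at",
        paste(signif(x$cutpoints, 4), collapse = ", "), "\n")
  }
  print(x$leaves, row.names = FALSE)
  invisible(x)
}

#' Kaplan-Meier product-limit estimate
#'
#' Wrapper over [survival::survfit()] with right censoring.
#'
#' @param times Positive follow-up times.
#' @param events Event indicators (1/TRUE = death, 0/FALSE = censored).
#' @return Data frame `time, n_risk, n_event, n_censor, surv`.
#' @export
kaplan_meier <- function(times, events) {
  stopifnot(all(times > 0), length(times) == length(events))
  fit <- survival::survfit(survival::Surv(times, as.numeric(events)) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Log-rank test between survival groups
#'
#' Wrapper over [survival::survdiff()]; chi-square with k-1 degrees of
#' freedom. With no observed events the test is undefined and flagged rather
#' than computed.
#'
#' @param times Positive follow-up times.
#' @param events Event indicators.
#' @param groups Group labels (2 or more levels).
#' @return List `chi2`, `df`, `p_value`, `defined`.
#' @export
log_rank <- function(times, events, groups) {
  stopifnot(all(times > 0),
            length(times) == length(events),
            length(times) == length(groups))
  if (sum(as.numeric(events)) == 0) {
    return(list(chi2 = NA_real_, df = NA_integer_, p_value = NA_real_,
                defined = FALSE))
  }
  sd <- survival::survdiff(
    survival::Surv(times, as.numeric(events)) ~ factor(groups))
  df <- length(sd$n) - 1L
  list(chi2 = unname(sd$chisq), df = df,
       p_value = pchisq(sd$chisq, df, lower.tail = FALSE), defined = TRUE)
}

#' Cohort association report
#'
#' Runs the standard association battery on a cohort table: Spearman
#' correlations of heterogeneity proportions against the imaging predictors,
#' with a Bonferroni-Holm correction across the family, and recursive
#' partitioning of the unshared proportion by maximum focal-lesion size.
#'
#' @param cohort Data frame with (a subset of) columns `prop_unshared,
#'   prop_shared_diff, delta_cna, max_fl_cm, n_fl`.
#' @param alpha Family-wise level for the Holm decisions.
#' @return List `correlations` (data frame with Holm-adjusted p-values) and
#'   `partition` (a [recursive_partition()] of `prop_unshared` by
#'   `max_fl_cm`, or `NULL` when the columns are absent).
#' @export
cohort_associations <- function(cohort, alpha = 0.05) {
  outcomes <- intersect(c("prop_unshared", "prop_shared_diff", "delta_cna"),
                        names(cohort))
  predictors <- intersect(c("max_fl_cm", "n_fl"), names(cohort))
  rows <- list()
  for (o in outcomes) {
    for (p in predictors) {
      sa <- tryCatch(spearman_assoc(cohort[[p]], cohort[[o]]),
                     error = function(e) NULL)
      if (is.null(sa)) next
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = o, predictor = p, rho = sa$rho, p_raw = sa$p_value,
        n = sa$n, stringsAsFactors = FALSE)
    }
  }
  correlations <- if (length(rows) > 0L) {
    tab <- do.call(rbind, rows)
    adj <- holm_correction(tab$p_raw, alpha = alpha)
    tab$p_adjusted <- adj$p_adjusted
    tab$significant <- adj$significant
    tab
  } else {
    NULL
  }
  partition <- NULL
  if (all(c("max_fl_cm", "prop_unshared") %in% names(cohort))) {
    partition <- tryCatch(
      recursive_partition(cohort$max_fl_cm, cohort$prop_unshared,
                          alpha = alpha),
      error = function(e) NULL)
  }
  list(correlations = correlations, partition = partition)
}
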