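# GEP70 expression risk score: mean log2 expression of the 51 up-regulated
# signature genes minus mean log2 expression of the 19 down-regulated genes;
# scores >= 0.66 are high-risk. The 70 gene identities are not defined here —
# they are configuration inputs (the synthetic cohort fabricates disjoint
# placeholder sets).

#' GEP70 gene-set configuration
#'
#' @param up_genes Character vector of up-regulated signature genes
#'   (expected 51; a different size warns, it does not error).
#' @param down_genes Character vector of down-regulated signature genes
#'   (expected 19).
#' @param high_risk_threshold Score at or above which a sample is high-risk
#'   (default 0.66).
#' @return Object of class `gep70_config`.
#' @export
gep70_config <- function(up_genes, down_genes, high_risk_threshold = 0.66) {
  up_genes <- as.character(up_genes)
  down_genes <- as.character(down_genes)
  if (length(up_genes) == 0L || length(down_genes) == 0L) {
    stop("up and down gene sets must be non-empty")
  }
  if (length(intersect(up_genes, down_genes)) > 0L) {
    stop("up and down gene sets overlap: ",
         paste(intersect(up_genes, down_genes), collapse = ", "))
  }
  if (length(up_genes) != 51L || length(down_genes) != 19L) {
    warning("gene-set sizes ", length(up_genes), "/", length(down_genes),
            " differ from the canonical 51 up / 19 down")
  }
  structure(list(up_genes = up_genes, down_genes = down_genes,
                 high_risk_threshold = high_risk_threshold),
            class = "gep70_config")
}

#' GEP70 score of one expression profile
#'
#' `mean(log2 expression of up genes) - mean(log2 expression of down genes)`.
#' Input must already be on log2 scale (normalization is upstream of this
#' package).
#'
#' @param expression Named numeric vector, gene -> log2 expression.
#' @param config A [gep70_config()].
#' @return Scalar score.
#' @export
gep70_score <- function(expression, config) {
  stopifnot(inherits(config, "gep70_config"))
  genes <- c(config$up_genes, config$down_genes)
  missing <- setdiff(genes, names(expression))
  if (length(missing) > 0L) {
    stop("expression profile is missing configured gene(s): ",
         paste(missing, collapse = ", "))
  }
  vals <- expression[genes]
  if (any(!is.finite(vals))) {
    stop("non-finite expression value(s) for configured gene(s): ",
         paste(genes[!is.finite(vals)], collapse = ", "))
  }
  mean(expression[config$up_genes]) - mean(expression[config$down_genes])
}

#' GEP70 scores and risk calls for an expression matrix
#'
#' @param expr Numeric matrix or data frame, genes in rows (rownames = gene
#'   names), samples in columns, log2 scale.
#' @param config A [gep70_config()].
#' @return Data frame `sample, score, risk` (`"high"` iff
#'   `score >= high_risk_threshold`).
#' @export
gep70_scores <- function(expr, config) {
  expr <- as.matrix(expr)
  scores <- vapply(colnames(expr), function(s) {
    gep70_score(setNames(expr[, s], rownames(expr)), config)
  }, numeric(1))
  data.frame(sample = colnames(expr), score = unname(scores),
             risk = ifelse(scores >= config$high_risk_threshold, "high", "low"),
             stringsAsFactors = FALSE)
}

#' Between-site GEP70 risk discordance
#'
#' @param scores Named (or unnamed) numeric vector of per-site GEP70 scores
#'   for one patient; needs at least two sites.
#' @param threshold High-risk threshold (inclusive), default 0.66.
#' @return `"concordant_high"` (all sites high-risk), `"concordant_low"`
#'   (none), `"single_site_high"` (some but not all), or `"not_evaluable"`
#'   (fewer than two sites).
#' @export
risk_discordance <- function(scores, threshold = 0.66) {
  scores <- scores[!is.na(scores)]
  if (length(scores) < 2L) return("not_evaluable")
  high <- scores >= threshold
  if (all(high)) "concordant_high"
  else if (!any(high)) "concordant_low"
  else "single_site_high"
}
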