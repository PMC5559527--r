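# Neutral-growth simulators. Two routes:
#  * "exact": inverse-CDF sampling from the 1/f^2 mutation-frequency density,
#    parameterized directly by the spectrum slope mu/beta, with a
#    deterministic-quantile mode for noise-free checks;
#  * "branching": a Yule (pure-birth) process. A lineage founded by one cell
#    when the population has size j ends, via the Polya-urn embedding, at a
#    final cell fraction distributed Beta(1, j); mutations arise at each
#    division as Poisson(mutation_rate).

#' Sample VAFs from the neutral 1/f spectrum
#'
#' Under neutral growth the expected cumulative spectrum is
#' `M(f) = slope * (1/f - 1/f_hi)` over `vaf_range = (f_lo, f_hi)`, i.e. the
#' VAF density is proportional to `1/f^2`. The number of mutations is the
#' expected in-range count `round(slope * (1/f_lo - 1/f_hi))`.
#'
#' @param slope Spectrum slope mu/beta (mutations per effective cell
#'   division), > 0.
#' @param vaf_range `(f_lo, f_hi)` truncation of the spectrum.
#' @param deterministic If `TRUE`, return the exact spectrum quantiles
#'   `f_i = 1 / (i/slope + 1/f_hi)` so that `M(f_i) = i` exactly (a noise-free
#'   realization with R-squared 1 by construction); otherwise sample by
#'   inverse CDF.
#' @return Numeric vector of VAFs.
#' @export
sample_neutral_vafs <- function(slope, vaf_range = c(0.05, 0.5),
                                deterministic = FALSE) {
  stopifnot(slope > 0, length(vaf_range) == 2L,
            vaf_range[1] > 0, vaf_range[1] < vaf_range[2], vaf_range[2] <= 1)
  f_lo <- vaf_range[1]; f_hi <- vaf_range[2]
  n <- round(slope * (1 / f_lo - 1 / f_hi))
  if (n == 0L) return(numeric(0))
  if (deterministic) {
    i <- seq_len(n)
    return(1 / (i / slope + 1 / f_hi))
  }
  u <- runif(n)
  1 / (1 / f_lo - u * (1 / f_lo - 1 / f_hi))
}

#' Simulate one sample's variant table under neutral growth
#'
#' Generates true VAFs either from the exact 1/f sampler or from a Yule
#' branching process, then draws alt reads binomially at the sequencing
#' depth. Mutations whose true VAF falls below `vaf_range[1]` (exact sampler)
#' or `vaf_min` (branching) are not emitted: they sit below any realistic
#' read-count support and would only inflate the table.
#'
#' @param n_cells_final Final tumor population size for the branching
#'   process (>= 100; ignored by the exact sampler).
#' @param mutation_rate For `method = "exact"`, the spectrum slope mu/beta;
#'   for `"branching"`, the Poisson mean number of new mutations per cell
#'   division. Must be > 0.
#' @param depth Mean sequencing depth (> 0).
#' @param seed Integer seed; same seed, same output.
#' @param method `"exact"` or `"branching"`.
#' @param vaf_range Truncation for the exact sampler.
#' @param vaf_min Emission floor for the branching process.
#' @param depth_model `"fixed"` or `"poisson"`.
#' @param purity Tumor purity; true VAFs are scaled by it (diploid, germline
#'   copy number 2, heterozygous: cell fraction q maps to VAF q*p/2... see
#'   Details).
#' @details With a diploid genome and purity `p`, a mutation in cell fraction
#'   `q` of the tumor has expected VAF `q * p / 2` (one mutated copy among
#'   the two tumor plus two germline copies weighted by purity); the exact
#'   sampler draws VAFs directly, so purity is applied multiplicatively as
#'   `f * p`.
#' @return Data frame `mutation_id, vaf_true, depth, alt_reads, vaf_obs`.
#' @export
simulate_neutral_spectrum <- function(n_cells_final = 1e4,
                                      mutation_rate = 20,
                                      depth = 150,
                                      seed = 1L,
                                      method = c("exact", "branching"),
                                      vaf_range = c(0.05, 0.5),
                                      vaf_min = 0.01,
                                      depth_model = c("fixed", "poisson"),
                                      purity = 1) {
  method <- match.arg(method)
  depth_model <- match.arg(depth_model)
  if (mutation_rate <= 0) stop("mutation_rate must be > 0")
  if (depth <= 0) stop("depth must be > 0")
  if (method == "branching" && n_cells_final < 100) {
    stop("n_cells_final must be >= 100")
  }
  set.seed(as.integer(seed))

  vafs <- if (method == "exact") {
    sample_neutral_vafs(mutation_rate, vaf_range) * purity
  } else {
    # Yule process via the Polya-urn embedding: division j takes the
    # population from j to j+1 cells and adds Poisson(mutation_rate) new
    # mutations to one daughter; that lineage's final fraction ~ Beta(1, j).
    n_new <- rpois(n_cells_final - 1L, mutation_rate)
    founders <- rep.int(seq_len(n_cells_final - 1L), n_new)
    frac <- rbeta(length(founders), 1, founders)
    f <- frac * purity / 2
    f[f >= vaf_min]
  }
  n <- length(vafs)
  d <- if (depth_model == "fixed") rep(round(depth), n) else rpois(n, depth)
  d <- pmax(d, 1L)
  alt <- rbinom(n, d, pmin(vafs, 1))
  data.frame(mutation_id = sprintf("neut_%05d", seq_len(n)),
             vaf_true = vafs, depth = d, alt_reads = alt,
             vaf_obs = alt / d, stringsAsFactors = FALSE)
}
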