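---
title: "Methods: quantifying spatial genomic heterogeneity in multiple myeloma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying spatial genomic heterogeneity in multiple myeloma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialmm)
```

## The problem

Multiple myeloma grows in the bone marrow, and clinical diagnosis usually
rests on a single "blind" aspirate from the iliac crest. Whole-body imaging,
however, shows focal lesions (FLs) — circumscribed accumulations of malignant
plasma cells — whose regionally restricted growth raises the question of
whether the genome sampled at the iliac crest represents the disease
elsewhere. `spatialmm` implements an analysis chain for *multi-region*
sequencing of paired specimens (an iliac-crest random aspirate and one or
more CT-guided fine-needle aspirates of FLs): it quantifies how much of each
patient's mutational and copy-number landscape is shared between sites, asks
whether per-sample VAF spectra are compatible with neutral growth, scores
site-specific expression risk, and tests cohort-level associations between
heterogeneity and imaging features.

Because the corresponding patient-level sequencing data are controlled
access, the package ships a synthetic multi-region cohort generator with a
fully known clonal ground truth. All quantitative claims made by the test
suite and the acceptance script are statements about that generator's output,
computed at run time.

## Cancer clonal fraction

For each mutation and sample, the observed VAF $f_s$ is converted to a
mutation copy number

$$n_{\mathrm{mut}} = f_s \cdot \frac{1}{p}\left[p\,n^t_{\mathrm{locus}} + 2(1-p)\right],$$

with $p$ the tumor purity and $n^t_{\mathrm{locus}}$ the tumor total copy
number taken from the sample's segmented profile at the variant position.
The chromosome multiplicity $n_{\mathrm{chr}}$ is the value
$c \in \{1, \dots, C\}$ maximizing the binomial likelihood of the observed
alt count at the expected VAF of a clonal mutation on $c$ copies; the cancer
clonal fraction is $\mathrm{CCF} = n_{\mathrm{mut}} / n_{\mathrm{chr}}$,
capped at 1, with $\mathrm{CCF} \ge 0.8$ flagged clonal.

Design points that the published description leaves open, decided here and
configurable:

* **Candidate range $C$.** Candidates run to the major-allele copy number
  (total minus minor), falling back to the total copy number when no minor
  allele count is available. A mutation cannot sit on more copies than the
  major allele provides.
* **Capping.** CCF is reported on $[0,1]$ because it is a proportion of
  tumor cells; the uncapped $n_{\mathrm{mut}}$ is retained in the output for
  diagnostics.
* **Ties.** Tied multiplicity likelihoods resolve toward the smaller $c$,
  which yields the larger (more conservative for "subclonal" claims) CCF
  never being silently preferred — the smaller multiplicity is the
  parsimonious genotype.
* **Clipping.** Expected VAFs are clipped to $[10^{-6}, 1-10^{-6}]$ so that
  near-fixed variants keep a finite likelihood.
* **Germline term.** The $2(1-p)$ term fixes germline copy number at 2
  everywhere, including sex chromosomes — a known limitation, documented
  rather than patched, since the simulated genome is autosomal.
* **Homozygous-deletion conflicts** (reads observed on a locus with total
  copy number 0) are flagged and excluded from CCF computation instead of
  producing a number.

The multiplicity assignment systematically assumes clonal expected VAFs, so
a genuinely subclonal mutation on two copies would be mis-assigned; in
practice multiplicity above one arises when a mutation predates a gain of
its chromosome — a clonal configuration — and the synthetic generator
follows that biology.

## Mutation classification between sites

Variants first pass the inclusion filters: VAF at least 5% in at least one
sample of the patient, total coverage strictly exceeding 20x in *all*
samples of the patient, and position outside a configurable blacklist (in
real data: immunoglobulin loci). For each sample pair, a mutation is

* **detected** at $\ge 2$ alt reads and **negative** at $\le 1$ (a single
  read is noise);
* **unshared** when detected in one sample and negative in the other, with
  the detected sample's CCF $\ge 0.2$ and the negative sample's total depth
  $\ge 50$;
* **shared-diff** when detected in both with at least a three-fold CCF
  difference and the larger CCF $\ge 0.2$;
* **shared** when detected in both otherwise;
* **unclassified-heterogeneous** when a heterogeneous pattern fails one of
  its floors — these count toward the mutation total but never toward a
  heterogeneity class, which keeps the heterogeneity proportions
  conservative.

With the default 2-read floor, the smallest detectable VAF at the minimum
qualifying negative-side depth of 50x is exactly 4%, which converts through
the CCF equation to an 8% CCF floor for a diploid locus at purity 1 and
multiplicity 1.

Decisions taken where the published rules are silent: the CCF floor applies
to the *positive* (respectively larger-CCF) side; a detected mutation with
CCF 0 on the lower side yields an infinite fold change and is shared-diff if
the larger CCF clears 0.2; with more than two samples, classification is per
pair and a mutation's patient-level label is its most heterogeneous pair
label (unshared > shared-diff > unclassified > shared), each mutation
counted once. The 5% VAF filter is interpreted as "at least 5% in at least
one sample", and "coverage exceeding 20x" as a strict inequality.

## Copy-number discordance

Segmented profiles are reduced to events (gain, loss, or copy-neutral LOH —
total copy 2 with minor allele 0 — relative to a diploid baseline), merging
adjacent same-state segments. The published analysis does not define when
two segments in different samples are "the same CNA"; this package uses
reciprocal 50% overlap of same-kind events, configurable. The unshared count
$\Delta$CNA keeps events private to one profile, longer than 1 Mb (strict),
and clonal (clonal fraction $\ge 0.8$) in the carrying sample — the 0.8
mirrors the mutation clonality convention, since the source text requires
only "clonal in at least one sample" against a ~20% subclone detection
floor. Gene-level deletion flags use a 10 kb floor for high-resolution
profiles and 1 Mb for WES-only profiles, with bi-allelic status from total
copy 0 or a caller-reported co-occurring mutation.

## Neutral-evolution test

Under neutral growth the cumulative number of subclonal mutations at VAF
$\ge f$ is linear in inverse frequency:

$$M(f) = \frac{\mu}{\beta}\left(\frac{1}{f} - \frac{1}{f_{\max}}\right),$$

with slope $\mu/\beta$, the mutation rate per effective cell division. A
sample is eligible when at least 12 SNVs have VAF strictly inside
$(0.12, 0.24)$ (exclusive bounds, matching the interval notation); the fit
is zero-intercept ordinary least squares of $M(f)$ on $1/f - 1/f_{\max}$,
and $R^2 \ge 0.98$ is called neutral. Conventions fixed here: $f_{\max}$
defaults to the window upper bound 0.24; $R^2$ is $1 - SS_{res}/SS_{tot}$
with $SS_{tot}$ about the mean of $M$ (zero-intercept $R^2$ conventions
differ, so this is stated explicitly) and clamped below at 0; duplicate VAFs
collapse to one support point with step height $> 1$; the fit is per support
point, not binned.

## Synthetic cohort generator

A patient is a rooted star tree: a founder clone carrying the clonal
mutations and canonical CNAs (del(13q), gain(1q)), and subclones carrying
private mutations and a private del(17p). Site compositions assign each
clone a cell fraction per specimen; a subclone is seeded at a site with
probability 0.6 and unseeded clones have fraction exactly 0, which is what
makes regionally restricted ("unshared") mutations possible. For mutation
$m$ at site $s$ the expected VAF is

$$E[f_{ms}] = \frac{\mathrm{CCF}_{ms}\, n_{\mathrm{chr},m}\, p_s}{p_s\, n_{\mathrm{locus}} + 2(1-p_s)},$$

with $\mathrm{CCF}_{ms}$ the summed fraction of clones carrying $m$. Alt
reads are binomial at the realized depth plus error reads at the per-base
error rate.

Defaults are the emulated study conditions: two sites, purity 0.9
(CD138-enriched aspirates), mean depth 129x with Poisson variation (the
emulated cohort's average; a fixed-depth mode exists for exact tests),
per-base error $10^{-3}$ (which exercises the single-read noise rule), and
50 mutations split evenly between founder and subclones (the emulated
cohort's median non-silent burden). SNVs are placed outside the CNA
intervals so the closed-form expected VAF (which assumes one locus copy
number for all tumor cells) is exact; CNAs still drive the $\Delta$CNA
analyses. The per-site GEP70 target scores are realized exactly by
recentring the fabricated up-gene set, and the maximum FL diameter is an
increasing noisy function of the injected unshared fraction (0.8 cm + 5 cm
per unit fraction, Gaussian noise SD 0.3 cm), so the cohort-level
association has a real signal to recover; the per-patient FL count is
Poisson with mean 18, the emulated cohort's average, and deliberately
carries no heterogeneity signal.

Two neutral simulators are provided. The *exact* route samples VAFs from
the $1/f^2$ density by inverse CDF, truncated to (0.05, 0.5), and is
parameterized directly by the slope $\mu/\beta$; its deterministic-quantile
mode places $f_i$ so that $M(f_i) = i$ exactly, giving a noise-free spectrum
with $R^2 = 1$ by construction for titration tests. The *branching* route is
a Yule (pure-birth) process through its Pólya-urn embedding — a lineage
founded by one cell when the population has $j$ cells ends at a final
fraction $\mathrm{Beta}(1, j)$ — with Poisson($\mu$) mutations per division.
The default $\mu/\beta = 20$ corresponds to roughly 360 subclonal variants
above 5% VAF and ~80 in the fit window, a mutation-rich but realistic
whole-exome burden; it was fixed once as the study condition for all
neutral-growth checks.

What the generator does **not** emulate: mapping and base-quality artifacts,
strand bias, germline contamination in the variant table, subclonal
copy-number interactions with SNV loci, translocations, and
microenvironmental structure. Passing tests therefore demonstrate that the
implementation recovers what it injects under clean binomial read models —
not that the thresholds are optimal for any particular real cohort.

## Cohort statistics

Spearman correlation, the Mann-Whitney Wilcoxon test, Holm's step-down
adjustment (family-wise 0.05, two-sided), the Kaplan-Meier product-limit
estimator and the log-rank test are delegated to R's `stats` and `survival`
packages behind thin interfaces that add the package's error handling
(constant vectors yield flagged undefined correlations, all-censored data a
flagged undefined log-rank — never a silent 0). The test suite validates
these paths against independent enumeration and hand-computed oracles.

The original analysis partitioned heterogeneity by FL size with conditional
inference trees. This package substitutes a deliberately simple,
deterministic procedure: at each node, every midpoint between consecutive
distinct predictor values is scored by a two-sided Wilcoxon rank-sum test
between the two resulting groups (minimum node size 5), and the best
cutpoint is accepted only if its Bonferroni-adjusted p-value — adjusted over
the node's candidate cutpoints — is below 0.05, recursing on both children.
This is a reimplementation choice, verified on simulated-recovery behavior
only: on strong two-changepoint data (steps at 1.0 and 2.5 cm) it recovers
both cutpoints in well over 90% of runs, and under pure noise it rarely
splits at all.

## Problem sizes and numerics

The default test and demonstration scale — cohorts of 6–12 patients at ~50
mutations each, 1,000-mutation parameter-recovery sweeps, 20-seed neutral
panels, 30-replicate partition recovery — was chosen so the entire suite
exercises every code path in well under a minute of simulation time while
keeping Monte-Carlo standard errors far below the tolerances asserted.
Larger cohorts only narrow the sampling error around the same expectations.

Degenerate inputs are handled explicitly throughout: empty windows yield
empty spectra; a single distinct in-window VAF yields a defined $R^2$;
zero-denominator proportions are `NA` (undefined), never 0; profiles
declaring different genome builds are rejected; and every random quantity in
the package flows from a single integer seed per patient or per run, so
identical configurations are byte-identical on disk.
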