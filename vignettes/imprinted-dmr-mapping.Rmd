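---
title: "Mapping imprinted DMRs from parental-dosage methylation arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping imprinted DMRs from parental-dosage methylation arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imprintscan)
```

## The dosage model

Genomic imprinting marks a locus with parent-of-origin-specific DNA
methylation. On a β-value array (β = methylated signal fraction, 0–1), a
cell population with $n_m$ maternal and $n_p$ paternal haploid genomes is
expected to show, at a maternally methylated locus with allele levels
$m_1$ (methylated origin) and $m_0$ (the other allele),

$$\beta = \phi\,\frac{n_m m_1 + n_p m_0}{n_m + n_p} + (1-\phi)\,\frac{m_1+m_0}{2},$$

where $\phi \in [0,1]$ is the *imprinting fidelity* — the fraction of
cells actually carrying the imprint. With $\phi = 1$, $m_1 = 1$, $m_0 = 0$
this gives 1/3 in diandric placentas (1 + 2 genomes), 2/3 in digynic
(2 + 1), 1/2 in any biparental tissue and 0 in androgenetic moles (0 + 2):
a theoretical 33.3 % diandry–digyny difference whose *sign* encodes the
parental origin. Fidelity below 1 shrinks every group toward the
biparental mean, which is why the screen uses a 15 % threshold rather than
the theoretical 33.3 % — incomplete methylation of the silenced allele and
cell-type mixtures attenuate real differences (`expected_beta()` is
monotone in $\phi$, and $\phi = 0$ erases the group contrast entirely).

## The permutation screen

`sam_two_class()` computes the moderated difference statistic

$$d_i = \frac{\bar x_{i1} - \bar x_{i2}}{s_i + s_0}, \qquad
  s_i = \sqrt{\tfrac{1/n_1 + 1/n_2}{n_1+n_2-2}\,
  \left(\textstyle\sum_1 (x-\bar x_{i1})^2 + \sum_2 (x-\bar x_{i2})^2\right)}$$

with the fudge factor $s_0$ chosen by minimizing the coefficient of
variation of windowed MADs of $d$ across candidate quantiles of $s$
(quantile grid 0, 0.05, …, 1; up to 100 $s$-quantile windows). Below 100
usable probes this selection is unstable, so the implementation falls back
to a fixed percentile of $s$ (default the 5th); toy-scale examples should
request `s0_method = "fixed_percentile"` directly.

The null distribution comes from label permutations. Two-class
permutations are drawn as canonical sample subsets of size
$\min(n_1, n_2)$, which makes the permutation set — and hence q-values —
exactly invariant under swapping the two group labels (only the sign of
$d$ flips). When the requested permutation count reaches
$\binom{n}{n_{\min}}$ the set is enumerated exhaustively. The multiclass
statistic generalizes $d$ to

$$d_i = \frac{\sqrt{\left(\sum_k 1/n_k\right)\sum_k n_k(\bar x_{ik}-\bar x_i)^2}}
  {s_i + s_0},$$

which reduces *exactly* to $|d|$ of the two-class form at $k = 2$;
multiclass permutations are uniform shuffles of the label vector
(enumerated when the multiset-permutation count is small).

For every candidate cutoff $\delta$ (each observed $|d|$):

$$\widehat{FDR}(\delta) = \hat\pi_0\,
  \frac{\mathrm{mean}_b\,\#\{|d^{*b}| \ge \delta\}}{\#\{|d| \ge \delta\}},$$

and a probe's q-value is the smallest $\widehat{FDR}$ at any cutoff that
calls it (a cumulative minimum over the $|d|$-ordered cutoffs, so q is
monotone in $|d|$). The false-positive count is summarized across
permutations by its **mean** (the expected number of false positives);
a median summary is available via `sam_config(fdr_summary = "median")` but
is not the default because the median of these zero-inflated counts
collapses to zero at the top order statistics, where it would certify the
largest observed $|d|$ as q = 0 on fully null data about half the time.
$\hat\pi_0$ is the proportion of observed $d$ inside the central 50 %
window of the permuted statistic, divided by 0.5 and capped at 1; the
window is taken from per-permutation quartiles (median across
permutations), reflected symmetrically for the signed two-class statistic
so that $\hat\pi_0$ is relabeling-invariant.

Two practical properties of permutation FDRs are worth knowing. First,
the attainable FDR is floored by the permutation space: with 5 vs 5
samples there are only 252 distinct assignments, and the identity
assignment alone keeps every estimate above roughly 1/252 — a 0.1 % FDR
target needs study-sized groups (10 vs 10 gives 184,756). Second, the
estimator spends its error budget on the extreme null order statistics:
the largest null $|d|$ earns q ≤ 0.001 in roughly 0.1 % × (number called)
× (permutations) events per thousand, so occasional single false calls at
a 0.1 % target are expected behavior, with the realized false-discovery
proportion matching the nominal level in expectation.

## The screen and its filters

Candidates are probes with q ≤ 0.001 (inclusive) **and** |Δβ| > 0.15
(strict), where Δβ = mean(diandric) − mean(digynic) on group means;
Δβ > 0 designates a paternal DMR, Δβ < 0 a maternal one. Two reference
clauses then guard against secondary effects such as cell-composition
differences: the normal-placenta mean must lie in the *closed* interval
between the triploid means, and the CHM mean must be *strictly* closer to
the diandric mean (ties eliminate; when both clauses fail the first is
reported as the elimination reason). The particularly low CHM methylation
expected at maternal DMRs is visible in the output means but is
deliberately not an additional filter. Consistent calls are aggregated
into DMRs by (gene symbol, origin) — a gene carrying both origins yields
two DMRs; unannotated probes become singleton DMRs keyed by probe id; the
DMR span is the 1-based inclusive min–max of member probe positions
(single-probe DMRs span 1 bp, as the array gives point measurements).
CNV-interval overlap is reported as an annotation only.

Classification of DMRs across the tissue panel uses an *any member probe*
rule: a DMR is tissue-differential (multiclass SAM across brain, kidney,
muscle, midgestation placenta, maternal blood at the same 0.1 % FDR) or
gestation-changed (two-class SAM, midgestation vs term placenta) if any
member probe is called; placenta-specific if additionally some member
probe's placental mean exceeds the maximum non-placental tissue mean by
strictly more than 0.15 (raw means, no uncertainty); stable iff neither.
The any-probe rule is the aggregation consistent with probe counts
exceeding DMR counts in such tables. Midgestation placentas represent the
placenta in the tissue panel.

## The synthetic generator

`simulate_dataset()` draws, per probe class and group, a noise-free
expected β and then logit-normal observations
$\mathrm{logit}^{-1}(\mathrm{logit}(\beta_{exp}) + N(0, \sigma))$
(expected values clamped to $[10^{-6}, 1-10^{-6}]$ before the logit;
$\sigma = 0$ returns expectations untouched, so degenerate-noise tests are
exact). Defaults mirror the study design: 10 diandric, 10 digynic, 10
normal-placenta, 6 CHM and 10 maternal-blood samples; 5,000 background
probes; 50 + 50 imprinted probes at full fidelity. Choices the data do not
dictate, made once: logit-scale noise sd 0.05 (β-scale sd ≈ 0.01 near
β = 0.5, matching well-behaved array replicates, and respecting the [0,1]
bounds with mean-level-dependent variance); a two-component background
mixture centred at β = 0.10 and 0.85 (weight 0.7 low, logit sd 0.6)
reflecting the bimodality of promoter methylation; tissue-specific probes
at 0.5 in placental groups vs 0.2 elsewhere (margin 0.3); gestational
drift 0.3 → 0.6; optional blood-divergent background (logit shift +1.5 in
maternal blood) so clustering tests can reproduce a blood/placenta split.
By construction the consistency pattern holds at every imprinted probe
(normal between the triploid expectations, CHM strictly closer to
diandric), so at zero noise the consistency filter retains 100 % of true
imprinted probes.

What the generator does *not* emulate: probe-type chemistry biases and the
nonlinear β response of real arrays, spatially correlated probes within a
promoter, CNV-driven artefacts, polymorphic imprinting, or realistic
cell-composition gradients. Passing tests therefore demonstrate that the
statistics and filters behave as designed under the dosage model — not
that real-array probe counts will reproduce exactly; on the deposited
real data unstated upstream settings (normalization, exact SAM
configuration) can shift counts by a few probes.

## Numerical and policy details

- β validation tolerates 1e-9 float dust outside [0,1], then clamps.
- Missing β cells are allowed; group means and correlations use available
  (pairwise-complete) values; SAM drops probes with any missing value,
  with a warning.
- Detection filtering is all-samples-strict (a single detection p above
  0.05 removes the probe); missing detection p counts as a failure.
- Welch's unequal-variance t-test is the census default (pooled variance
  available); probes constant everywhere yield p = 1, zero-variance
  probes with different means p = 0.
- Clustering distance is 1 − Pearson r with average linkage (complete
  available); columns are sorted by sample id first so the result does
  not depend on input order.
- Thresholds follow their printed forms: q ≤ 0.001 inclusive, |Δβ| > 0.15
  strict, placental margin > 0.15 strict, monoallelic ratio < 0.3 strict,
  clone conversion ≥ 0.8 inclusive.
- BED output is 0-based half-open; annotation positions are 1-based; the
  two conversions are exact inverses. BED scores are
  `round(1000 · |mean Δβ|)` purely for browser display.

## Problem sizes used by the test suite

The packaged tests run the calibration experiments at 5,000 null probes,
10 vs 10 samples, 500 permutations and 20 seeds (null and mixed), the
acceptance script at 1,000 permutations; unit tests use a few hundred
probes. These sizes were chosen as the smallest at which the permutation
space supports the 0.1 % FDR target and Monte-Carlo bounds are tight.

## Limitations

- Only symmetric |d| thresholds are implemented (no asymmetric delta
  cutoffs), and no paired, survival or time-course SAM variants.
- π0 uses the central-window convention; spline-based estimators may
  differ slightly.
- The exact configuration of the original screen's software is not
  recoverable; defensible alternative settings (s0 selection, FDR
  summary) shift borderline probes.
- Real IDAT parsing, background correction and between-array
  normalization are out of scope: the package expects normalized β
  values.
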