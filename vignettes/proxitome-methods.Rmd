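---
title: "Statistical methods behind proxitome"
author: "proxitome authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind proxitome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxitome)
```

# The problem

A proximity-labeling experiment compares streptavidin pulldowns from cells
or tissue expressing a bait–biotin-ligase fusion against a freely
diffusing cytosolic ligase. The control defines the *spatial background*:
everything the ligase reaches by chance. A protein belongs to the bait's
interactome when its label-free quantification (LFQ) intensity is
systematically higher in the bait pulldown than in the control — not
merely detected, since abundant cytosolic proteins are biotinylated by any
ligase.

Three properties of LFQ data shape the pipeline:

* intensities are approximately log-normal, so all testing happens on the
  log2 scale;
* replicate counts are small (3–11 per group), so variance estimation is
  fragile and design choices err conservative;
* missingness is *missing-not-at-random*: proteins drop out when they fall
  below detection, so missing cells carry information (they were probably
  low) and imputation must reflect that.

# Pipeline stages and their assumptions

## Completeness filter

A protein is retained when the fraction of quantified values reaches
`min_valid_fraction` in at least one group (OR semantics). The one-sided
logic is deliberate: a protein quantified in every bait replicate and
never in the control is the strongest possible candidate, not a data
problem. With 3 replicates per group the default fraction is 1.0 (any
missingness is fatal at n = 3); larger tissue designs relax it to 0.75.
The filter trades sensitivity for testability: on the reference synthetic
condition below, 6–9% of truly enriched proteins are lost here, almost all
of them low-abundance proteins whose bait replicates were censored.

## Left-censored imputation

Remaining missing cells are drawn from
$\mathcal{N}(\mu_c - d\,\sigma_c,\ (w\,\sigma_c)^2)$ per sample column
$c$, where $\mu_c$ and $\sigma_c$ are the column's *observed* mean and
sample SD. The width $w < 1$ and downshift $d > 0$ place imputed values in
the lower tail of the abundance distribution — the values a
below-detection protein plausibly had. Defaults are $(w, d) = (0.5, 1.6)$
(cultured cells) and $(0.4, 1.7)$ (brain tissue), exposed as the
`n2a`/`brain` presets.

Column-wise moments are the default (`impute_mode = "column"`) because
each LC-MS run has its own abundance distribution; a whole-matrix mode is
available. Each column draws from a deterministic child stream derived
from the root seed and the *sample id*, so reordering columns cannot
silently reshuffle draws, and identical inputs give bitwise-identical
output.

Imputation from a downshifted distribution is mildly anticonservative for
proteins observed in one group and imputed in the other: it manufactures a
difference in exactly the direction the filter already suggested. This is
the accepted price of keeping such proteins testable; the null-calibration
analysis below therefore isolates the test stage from imputation.

## Welch test, z-scores, hit call

Per protein, Welch's unequal-variance $t$ on the log2 values with
Satterthwaite degrees of freedom and a two-sided p-value. Equal variances
are not assumed because bait enrichment itself changes abundance and hence
measurement variance.

The fold-change z-score standardizes each protein's log2 difference
against the population of differences. Because the vast majority of
proteins are background in a proximity-labeling design, the population
mean and SD estimate the null fold-change distribution, and `z > 1` acts
as an effect-size cutoff that p-values alone cannot provide at small n.
The z population is all proteins passing the completeness filter
(`z_population = "filtered"`), not only those with $p < \alpha$:
conditioning on significance first would inflate the population SD with
true positives and bias z downward. The alternative is provided as a
switch since the ordering is a genuinely open choice.

A hit must satisfy all three cutoffs *strictly*: $p < \alpha$,
$z > z_\text{cutoff}$, and a positive log2 difference (enrichment toward
the bait). Degenerate cases are defined, not errors: identical groups give
$t = 0, p = 1$; zero variance with unequal means gives $p = 0$ plus a
warning.

## CV quality control

Per-protein percent CV is $100\,s/\bar{x}$ over the *raw-scale, observed*
(never imputed) bait-group intensities — raw scale because CV is a
raw-scale concept, bait group because that is the signal being claimed,
observed-only because imputed values would fabricate reproducibility. The
dataset-level QC gate is the mean CV over the hit set staying below 30%;
a pooled-group CV mode is available.

# Power analysis

The design calculation treats the comparison as a two-tailed test of two
independent means. A raw-scale fold change $\mathit{fc}$ and replicate CV
convert to Cohen's $d$; power uses the exact noncentral $t$ (not the
normal approximation — at $n = 6$ the difference matters):
$\lambda = d\sqrt{n/2}$, $\mathrm{df} = 2n - 2$,
$\text{power} = P(|T'_{\mathrm{df},\lambda}| > t_{1-\alpha/2})$.

Two CV→SD conventions are supported because the effect-size formula fed
to a point-and-click power tool is rarely recoverable:

* `"lognormal"` (default, matching the pipeline's own scale):
  $\sigma_{\log_2} = \sqrt{\ln(1 + \mathrm{cv}^2)}/\ln 2$,
  $d = \log_2(\mathit{fc})/\sigma_{\log_2}$;
* `"raw"`: SD proportional to the mean at the pooled midpoint,
  $d = (\mathit{fc} - 1)/(\mathrm{cv}\,(1 + \mathit{fc})/2)$.

At the reference design point (n = 6, CV 30%, 2-fold, $\alpha = 0.05$)
they give powers of 0.957 and 0.933 — both above 0.90, so the design
conclusion is convention-robust. `min_n_for_power()` inverts the
calculation by doubling search plus integer bisection.

# The synthetic generator

`simulate_lfq()` emulates the statistical structure of a bait-vs-control
LFQ experiment: per-protein log2 baselines
$\mu_i \sim \mathcal{N}(\texttt{baseline\_mean}, \texttt{baseline\_sd}^2)$,
a fixed log2 effect added to bait replicates of a truly enriched minority,
Gaussian replicate noise whose SD maps exactly to a raw-scale CV through
the lognormal identity $\mathrm{cv} = \sqrt{e^{(s \ln 2)^2} - 1}$, and
left-censoring in which a cell at log2 value $v$ goes missing with
probability $\operatorname{logistic}((L - v)/s)$. The logistic form (rather
than a hard threshold, which is available as `censor_mode = "hard"`)
produces the MNAR pattern that downshifted imputation assumes while
keeping every protein testable.

The default scenario — the package's reference validation condition — is
5000 proteins, 5% enriched at 4-fold (`effect_log2 = 2`), 6 vs 6
replicates, `rep_sd = rep_sd_from_cv(0.20)` (20% CV, the typical in-vivo
biological replicate precision), baseline $\mathcal{N}(25, 2.5^2)$
(typical log2 LFQ dynamic range), and censoring at $L = 21.8$, $s = 0.5$,
which loses ≈ 10–12% of cells, concentrated in the lower abundance tail.
Published bait-over-control ratios motivate the effect scale: observed
enrichments run from about 2-fold to 50-fold, so a 4-fold default is a
representative mid-range effect, and an `effect_log2` range (e.g.
`c(1, 5.7)`) can be drawn uniformly per protein.

What the generator does **not** emulate: peptide-to-protein roll-up,
shared peptides, batch and run-order effects, cross-run normalization
artifacts, heavy-tailed contaminant intensities, or correlated protein
modules. Passing recovery tests therefore demonstrates that the pipeline's
statistics behave as designed under its own model assumptions — not that
any real dataset satisfies those assumptions.

# Numerical and reproducibility choices

* Sample SD ($n - 1$ denominator) everywhere — z-scores, CV, imputation
  moments — because n is small.
* Strict inequalities at every cutoff (`p < 0.05`, `z > 1`), so boundary
  values never pass.
* One root seed; per-column imputation streams keyed by sample id;
  `simulate_lfq()` fully determined by `(params, seed)`. Two runs from the
  same CLI manifest reproduce outputs byte for byte.
* The reported `ratio` is $2^{\bar{x} - \bar{y}}$, the geometric-mean
  ratio — the arithmetic produces a consistent pair (difference on log2
  scale, ratio on raw scale) rather than mixing scales.
* Enrichment tables are written with 12 significant digits; matrix TSVs
  with 17 (exact double round trip).

# Validation results and known limitations

The test suite validates every stage against independent oracles (exact
hand-derived cases, `stats::t.test`, exhaustive hypergeometric
enumeration, an independently coded BH step-up, Monte-Carlo power
simulation at $5 \times 10^4$ replicates) and the whole pipeline against
the generator's ground truth. Problem sizes were chosen to estimate each
quantity stably at interactive runtimes: recovery pools ten seeds of the
5000-protein reference condition (sensitivity 0.91, empirical FDR < 0.01
for the joint $p<0.05 \wedge z>1 \wedge d>0$ call); null calibration pools
twenty seeds of 1000 proteins at n = 3 vs 3.

Two limitations are worth stating plainly:

* **Welch's test is conservative at n = 3.** With both groups of size 3
  the Satterthwaite df never exceeds 4 and is usually below it, so the
  realized type-I error at nominal $\alpha = 0.05$ is ≈ 0.034 — for our
  implementation and for `stats::t.test` alike. Calibration checks at
  n = 3 should expect this deficit; the test is never anticonservative,
  which is the direction that matters for an interactome claim.
* **Null calibration is measured with censoring disabled.** With MNAR
  missingness plus downshifted imputation, one-group-imputed proteins pick
  up inflated differences; the measured null fraction under censoring
  reflects both effects entangled. The shipped check isolates the Welch
  stage. Users analyzing heavily censored data should read small p-values
  on heavily imputed proteins with corresponding suspicion (the
  `n_valid_*` columns make them easy to spot).

Out of scope by design: protein inference from precursor data,
match-between-runs, cross-run normalization (all upstream of this
package), GO-hierarchy-aware pruning of over-representation results, and
any network retrieval or visualization beyond the base volcano plot.
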