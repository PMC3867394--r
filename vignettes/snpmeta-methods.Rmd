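---
title: "Genetic-model meta-analysis with snpmeta: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic-model meta-analysis with snpmeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpmeta)
```

## The statistical model

A case-control genotype study of a biallelic marker reports six counts:
AA/AG/GG in cases and controls. A genetic-model contrast reduces them to a
2x2 exposure table; `snpmeta` implements the four standard ones —
homozygote (GG vs AA), heterozygote (AG vs AA), dominant (GG+AG vs AA),
recessive (GG vs AG+AA). For the homozygote and heterozygote contrasts the
excluded genotype column is dropped, not merged, so the per-contrast sample
sizes differ. The per-study effect is the log odds ratio with the Woolf
variance (sum of reciprocal cells), which assumes cell counts large enough
for the log OR to be approximately normal.

Pooling assumes the study-level estimates are independent. Three estimators
are provided:

* **Mantel–Haenszel fixed effects**, the ratio of summed cross-products,
  with the Robins–Breslow–Greenland variance. It is the preferred fixed
  estimator with sparse cells.
* **Inverse-variance fixed effects**, weights $w_i = 1/\mathrm{se}_i^2$.
* **DerSimonian–Laird random effects**, weights
  $w_i^* = 1/(\mathrm{se}_i^2 + \hat\tau^2)$ with the moment estimator
  $\hat\tau^2 = \max\{0, (Q - df)/(S_1 - S_2/S_1)\}$ computed from
  Cochran's $Q$ around the inverse-variance fixed pool.

Significance of the pooled log OR uses a two-sided Z test; 95% intervals
use the quantile 1.96 exactly, which is what reproduces published intervals
printed at two decimals.

## Estimator selection and a documented discrepancy

The conventional rule — fixed effects when the heterogeneity p-value
exceeds 0.10, random effects otherwise — is implemented as
`selection = "paper_rule"` and is the default. The comparison is strict, so
$P_h$ exactly 0.10 selects random effects (a boundary that essentially
never binds in practice and is pinned by a unit test).

For the bundled MCP-1 −2518A/G data set, however, the published stratum
estimates are reproduced (to the printed two decimals) by DerSimonian–Laird
random effects in *every* pinned stratum, including strata whose $P_h$
exceeds 0.10, where the stated rule would have chosen Mantel–Haenszel.
Since DL collapses toward the fixed pool as $\hat\tau^2 \to 0$, the two
coincide in low-heterogeneity strata (e.g. the prostate heterozygote
stratum, $P_h = 0.808$, where MH, IV and DL all print 0.81 (0.62, 1.07)).
The acceptance tests therefore pin `force_random` for reproduction, while
`paper_rule` stays the honest default for new analyses. Both policies are a
single flag apart throughout the interface.

## Hardy–Weinberg screening

Controls are tested with the 1-df Pearson $\chi^2$ (three genotype classes,
one estimated allele frequency), no continuity correction; deviation is
flagged at $p < 0.05$. Flagged studies are reported but **not** excluded
from pooling, matching how such studies are conventionally retained with a
sensitivity caveat. The df = 1 convention is confirmed by the bundled
data: the endometrial-cancer control series (124, 82, 5) gives $p = 0.042$,
matching its published flag, where df = 2 would give $p \approx 0.13$.

The Pearson HWE test is known to be anticonservative when expected
minor-homozygote counts are small: simulated controls drawn exactly under
Hardy–Weinberg at the bundled table's size/frequency regime reject at
roughly 7% rather than 5%, while at moderate sizes (400–1000 controls,
allele frequency 0.3–0.6) the empirical rate is within 1 percentage point
of nominal — the regime where the package's calibration test runs.

## The bundled data set, as printed

The fixture transcribes the published 19-study table exactly, including its
self-inconsistencies, which are documented rather than repaired:

* The Arshad 2013 control genotype counts (60, 87, 8) sum to 155, not the
  printed 190. On the printed counts that control series deviates from HWE
  ($p = 0.001$) although the published table flags it "Yes", and the
  all-study recessive bias tests give Egger $p = 0.93$ / Begg $p = 0.73$
  where the original analysis printed 0.96 / 0.67. Setting the control AA
  count to 95 (which restores the 190 total) reproduces both published
  bias p-values to within 0.01 — strong evidence of a misprint in the
  published row — but the package does not silently substitute
  unverifiable counts, so two acceptance tests assert the published values
  and fail, on purpose.
* The Sáenz-López 2008 control series (178, 123, 10) is internally
  consistent yet gives HWE $p = 0.039$, against its published "Yes" flag.
* The published abstract's control total (5,173) equals the genotype-count
  column sum; the per-study size column sums to 5,208 because of the
  Arshad row above.
* Two studies share one control series (the two Qin 2009 entries), and the
  published "Total" row prints N = 20 for 19 studies; the package keeps
  the rows independent, as pooled originally, and reports 19.

Subgroups follow the published conventions: digestive-system cancer is
exactly {oral, gastric, colorectal, hepatocellular}; "large" means strictly
more than 500 participants (cases + controls, computed from genotype
sums); ethnicity and control source are closed vocabularies. A study with
exactly 500 participants would be "small" — a literal reading of "more
than 500"; no bundled study sits on the boundary.

## Publication-bias tests

Egger's test is the classical unweighted OLS of the standardized effect
$y_i/\mathrm{se}_i$ on precision $1/\mathrm{se}_i$, with a two-sided t test
of the intercept on $k-2$ df. An exactly collinear configuration (zero
residual variance) is reported as intercept 0, $p = 1$ when the fit passes
through the origin. Begg's test standardizes deviations from the
fixed-effects pool by $\sqrt{\mathrm{se}_i^2 - 1/\sum w_j}$, rank-correlates
them with the variances (Kendall $\tau_b$ with tie-corrected variance), and
applies a continuity correction to the normal approximation — the variant
implemented in the major commercial meta-analysis packages. With all
variances equal every pair is tied and the test degenerates to $p = 1$.

## Meta-regression

The published analysis names meta-regression but not its estimator, so the
package makes its own documented choice: weighted regression of log ORs on
level indicators with a method-of-moments residual $\tau^2$
($\hat\tau^2 = \max\{0,(Q_E - (k-p))/\mathrm{tr}(P)\}$, the multivariable
analogue of DerSimonian–Laird) and a joint Wald $\chi^2$ test of the
non-reference coefficients. This matches `metafor`'s `method = "DL"`
moment estimator, which the test suite uses as an independent cross-check.
Because the original estimator is unidentifiable from the publication, its
meta-regression p-values are not reproduction targets. Each moderator is
analysed in its own univariate regression, mirroring the original's
one-factor-at-a-time phrasing.

## The synthetic generator

`sim_config()` / `simulate_studies()` emulate the fixture's structure:
control genotypes are multinomial under Hardy–Weinberg at a per-study
G-allele frequency drawn from `maf_range`; case genotype probabilities are
the control probabilities tilted by genotype odds ratios
$(1, \psi_{AG}, \psi_{GG})$. The tilt is the exact logistic model, so
$\psi_{GG}$ *is* the homozygote-contrast OR and $\psi_{AG}$ the
heterozygote one — recovery experiments have exact truths without a
rare-disease approximation. The dominant and recessive contrasts do not
have a constant induced OR under this model (their truth depends on the
allele frequency), so `recovery_experiment()` accepts them only under the
null. Between-study heterogeneity adds $u \sim N(0,\tau^2)$ to
$\log\psi_{GG}$, scaling $\log\psi_{AG}$ proportionally (half-effect under
a null $\psi_{GG}$).

Defaults mirror the bundled regime — 19 studies, 50–600 cases, 75–650
controls, control G-allele frequency 0.2–0.6, null effects — chosen once as
a realistic candidate-gene scenario. The generator deliberately omits
features of real literatures: shared control series, population
stratification, genotyping error, covariate confounding, and
publication-driven selection. Passing recovery tests therefore demonstrate
the estimators' statistical correctness under the stated model, not
robustness to those artifacts.

Calibration results the test suite computes at fixed seeds: the pooled
fixed-effects Z test rejects a true null in 3–5% of 1000 replicates at
k = 10 (DL is slightly conservative there, ~2.4%); the pooled log OR for a
true OR of 1.5 is unbiased to within 0.05 at k = 30 studies of ~500/500;
the heterogeneity p-value is near-uniform under homogeneity
($\Pr(P_h < 0.10) \approx 0.09$); DL coverage dominates fixed-effects
coverage at $\tau = 0.3$; and $\hat\tau^2$ recovers $\tau^2 = 0.09$ to
within 20% at k = 100 studies of 2000/2000. Replicate counts (150–1000)
were sized so each check pins its property with comfortable binomial
margins while the whole suite stays fast.

## Numerical conventions and degenerate inputs

* Zero cells: Haldane–Anscombe 0.5 added to all four cells, only for
  tables containing a zero; tables with an empty case or control margin
  are an error, not corrected. No bundled table triggers the correction,
  so it cannot perturb the reproduction results.
* $\hat\tau^2$ and $I^2$ floored at zero; $Q = 0$ reports $I^2 = 0$.
* Single-study "pools" return the study's own effect, flagged
  `single_study`; subgroup reports hide such rows in the formatted table
  (as publications typically do) while keeping them in the JSON.
* Monomorphic control samples report $\chi^2 = 0$, $p = 1$, flagged.
* Mantel–Haenszel and inverse-variance fixed pools agree closely only in
  the moderate-count regime; on sparse strata (cells below ~5) they can
  diverge by several percent, which is expected estimator behaviour, not a
  defect — the bundled bladder recessive stratum is such a case.

## Known limitations

Exact conditional HWE tests, Peto pooling, REML/Paule–Mandel $\tau^2$,
Hartung–Knapp intervals, trim-and-fill and selection models are out of
scope. The allele-count contrast (G vs A) is intentionally absent: the
analysis surface is the four genotype contrasts. Rendering is limited to
data tables (forest/funnel coordinates); no publication-quality plots.
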