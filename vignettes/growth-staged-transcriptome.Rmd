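---
title: "Methods: growth-curve staging and the stage-profiled transcriptome workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth-curve staging and the stage-profiled transcriptome workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curvestage)
```

This vignette is the package's account of its models, numerical choices
and limitations. It states no empirical result beyond what the test
suite and the analysis scripts themselves compute.

## Sigmoid growth models and closed-form staging

Three three-parameter families describe saturating growth, written with
asymptote `A` (kg), shape `b` (dimensionless) and rate `k` (per day):

* logistic \(y = A/(1 + b e^{-kt})\)
* Gompertz \(y = A e^{-b e^{-kt}}\)
* Von Bertalanffy \(y = A(1 - b e^{-kt})^3\)

All derivatives factor through the substitution \(u = b e^{-kt}\) (with
\(du/dt = -ku\)), giving polynomials in `u`:

| family | \(y'\) | \(y''\) | \(y'''\) |
|---|---|---|---|
| logistic | \(Aku/(1{+}u)^2\) | \(-Ak^2u(1{-}u)/(1{+}u)^3\) | \(Ak^3u(u^2{-}4u{+}1)/(1{+}u)^4\) |
| Gompertz | \(Akue^{-u}\) | \(-Ak^2u(1{-}u)e^{-u}\) | \(Ak^3u(u^2{-}3u{+}1)e^{-u}\) |
| Von Bertalanffy | \(3Aku(1{-}u)^2\) | \(-3Ak^2u(1{-}u)(1{-}3u)\) | \(3Ak^3u(9u^2{-}8u{+}1)\) |

The staging points are therefore parameter-free in `u` and closed-form
in `t = log(b/u)/k`:

* **MGI** (maximum growth rate; root of \(y''\)): \(u = 1, 1, 1/3\);
  maximum rate \(Ak/4\), \(Ak/e\), \(4Ak/9\); weight fraction at MGI
  \(1/2\), \(1/e\), \(8/27\) of `A`.
* **GRI / RSI** (roots of \(y'''\)): \(u = 2 \pm \sqrt3\),
  \((3 \pm \sqrt5)/2\), \((4 \pm \sqrt7)/9\) (larger `u` is the earlier
  age).

`inflection_points()` evaluates these and *self-checks* each root
against the analytic derivative it should annihilate (relative to the
natural scale \(Ak^{\mathrm{order}}\), tolerance `1e-8`); the test suite
additionally confirms every closed form against bracketing bisection on
the analytic derivatives to \(|\Delta t| < 10^{-6}\) days. Two
independent routes — algebra and root-finding — must agree, so an error
in either is caught by the other.

Degenerate geometry is flagged, not hidden: a logistic model with
\(b < 2+\sqrt3\) (or a Von Bertalanffy with \(b < (4+\sqrt7)/9\)) puts
the GRI before birth; the report carries a `negative_age` flag and a
warning. A Von Bertalanffy model with \(b \ge 1\) is accepted but only
meaningful for \(t \ge \log(b)/k\).

Ages are in days and weights in kg throughout; the maximum rate is
reported in g/day (×1000) because daily gain is conventionally quoted in
grams. Stage assignment uses half-open intervals — GIS up to and
including the GRI age, RIS up to and including the RSI age, SIS beyond —
making the partition exhaustive and non-overlapping.

## Fitting and model selection

`fit_growth_model()` minimizes \(\sum_i (w_i - y(t_i))^2\) by
Levenberg–Marquardt damped least squares (via `minpack.lm::nls.lm`) with
analytic residual Jacobians, on the log-parameter scale so `A`, `b`,
`k` remain positive. Sigmoid least squares is multimodal in `(b, k)`,
so eight restarts are run from a data-driven initial guess —
\(A_0 = 1.2\max(w)\), \(b_0\) from the earliest-age weight, \(k_0\)
from the slope of the family's log-linearization — jittered with seeded
Gaussian noise (sd 0.3 on the log scale); the converged restart with the
lowest SSE wins. Convergence is the optimizer's gradient/step criterion;
a fit that never converges is returned with `converged = FALSE` rather
than as an error, so callers can still inspect it.

R² is computed on raw, untransformed weights (no weighting), and can be
negative for models worse than the mean. `select_best_model()` picks the
converged fit with the highest R²; all families have three parameters,
so no complexity penalty applies, and exact ties fall back to the fixed
order logistic < Gompertz < Von Bertalanffy.

The fit accepts either per-timepoint means or the full animal-by-
timepoint record set; with the default generator (126 animals × 19
shared timepoints) both shapes give the same least-squares problem up to
a constant.

## Expression profiling

CPM uses the column totals of the supplied matrix as library sizes
(mapped-read totals are not recoverable from a count matrix; externally
supplied sizes are accepted). The expressed set keeps features with
CPM strictly greater than 0.5 in at least one library; per-stage
detection applies the same rule restricted to each stage's three
libraries (the within-stage reading of the rule — the cross-library
alternative is a one-argument change). Sample structure is assessed on
`log2(CPM+1)`: average-linkage hierarchical clustering on
`1 − Pearson` distance (metric and linkage are deliberate, documented
choices; the distance is bounded in [0, 2] and insensitive to depth),
and PCA with features centered across samples and no scaling.

## Differential expression

The two contrasts are GRI–MGI and RSI–MGI, each with its own BH
correction. The effect estimate is
\(\log_2((\bar{\mathrm{CPM}}_a + 0.5)/(\bar{\mathrm{CPM}}_b + 0.5))\).
The test normalizes counts by library-size ratios, estimates a
per-feature dispersion by method of moments
\(\phi = \max(0, (s^2-\mu)/\mu^2)\) pooled across the two groups, and
forms a Wald statistic with the delta-method standard error of the log2
fold change, \(\mathrm{Var}(\bar x_g) = (\mu_g + \phi\mu_g^2)/n_g\).

With three replicates per group a raw moment dispersion is far too
noisy to calibrate a Wald test: the normal reference is anticonservative
and a t with the residual 4 degrees of freedom overshoots the other way.
The test therefore moderates the dispersion empirical-Bayes style —
shrinking toward the median dispersion of expressed features with a
prior weight of 10 degrees of freedom, the same order as the established
count-model packages use — and refers the statistic to a t distribution
with residual + prior degrees of freedom. Under the generator's null
(negative binomial, equal means, dispersions 0.02–0.2) this holds the
type-I error near the nominal 0.05, which the acceptance suite checks on
2000 null features.

Calls are strict: `up` requires `log2FC > 1` *and* `q < 0.1`; a fold
change of exactly 1 is not significant. All-zero features get `p = 1`.

## cis-target windows

Distance between a lncRNA and a gene is the number of bases strictly
between their nearest interval ends (0 for overlapping or adjacent
intervals), on 0-based half-open coordinates; a pair is emitted when the
gap is at most the window (boundary inclusive, default 100 kb), strand
ignored. The query runs on sorted interval machinery
(GenomicRanges/IRanges); the tests hold it equal to an all-pairs brute
force, including gaps of exactly `window` and `window + 1`.

## Candidate screen

Pearson tests use the exact t-transform \(t = r\sqrt{n-2}/\sqrt{1-r^2}\)
with two-sided p-values, also callable from summary `(r, n)` pairs so
published coefficients can be re-tested. The default significance level
is 0.05 two-sided (configurable). `2^-ΔΔCt` quantification is exact
arithmetic and shift-invariant in Ct.

Seed matching implements the four canonical site classes — 6mer
(reverse complement of miRNA positions 2–7), 7mer-m8 (2–8), 7mer-A1
(2–7 plus an A opposite position 1) and 8mer (2–8 plus that A) — with
U/T equivalence and all overlapping occurrences reported. By default
each locus is reported once at its maximal class; `collapse = FALSE`
exposes the nested matches. This is a sequence-complementarity stand-in
for free-energy hybridization tools: it ranks candidate loci and, with
the Altschul–Erickson dinucleotide-preserving shuffle as a permutation
null, attaches an empirical significance to the observed site count.
It does not model pairing energetics or site accessibility.

## Synthetic data: what it emulates and what it does not

The generators are pure functions of a config and a seed (byte-identical
reruns, caller RNG state restored):

* **Weights**: `w = y(t)(1+ε)`, ε Gaussian with sd `cv_noise` (default
  5%, truncated to keep weights positive), for 126 animals × 19
  timepoints spanning 0–400 days around a Von Bertalanffy truth with the
  published parameter triple as default. Multiplicative noise reflects
  that weighing error and animal-to-animal variation scale with size.
* **Counts**: log-normal baselines (log2 mean 5, sd 2) over 2000 mRNAs
  and 1000 lncRNAs — a deliberately scaled-down transcriptome that keeps
  the suite fast while leaving thousands of null features for
  calibration — with lncRNA baselines shifted 2 log2 units down (so the
  lower average lncRNA abundance emerges from the pipeline rather than
  being asserted), 10% DE at ±2 log2FC split 60/40 between the GRI and
  RSI contrasts (the earlier contrast carries more change), NB
  dispersion 0.05, depth jitter ±20%.
* **Annotation**: isolated lncRNA–gene cassettes with planted gaps that
  always include 0, window−1, window and window+1, so the boundary
  convention is exercised by construction.
* **Panel**: a Gaussian latent factor with loadings solved so the
  population correlation equals the target (default |r| = 0.6, n = 47,
  6 positive and 4 negative correlates).

What passing tests on these data show is that the *pipeline logic* is
correct and calibrated under its stated model. What they cannot show:
real library-size estimation from mapped reads, count overdispersion
heterogeneity and outliers, batch structure, transcript-assembly noise
in lncRNA annotation, or sequence realism beyond composition — so
agreement with the generators is a necessary, not sufficient, condition
for correctness on real data. Published tallies that depend on the
original libraries (total DEG/DEL counts, per-stage detection totals)
are outside what desk reproduction can check; the pipeline reproduces
their *form* (per-biotype, per-contrast summaries) and the qualitative
structure (GRI apart from MGI/RSI; lncRNA below mRNA in abundance).

## Problem sizes and tolerances

The suite runs at: 100 random parameter sets per family for the
bisection oracle (|Δt| < 1e-6 d); 20 seeded herd replicates for
parameter recovery (median relative error < 5%, family selection ≥
80%); 2000 null features for test calibration (type-I 0.05 ± 0.02);
1000 random p-vectors for the BH oracle; 200 toy annotations for the
window oracle; 1000 dinucleotide shuffles for the seed-site null. Golden
staging numbers are compared at relative 5×10⁻³ (1×10⁻² for the
smallest weight) because the published parameters carry three decimals —
the reproducibility limit is parameter rounding, not the algorithm.

## Known limitations

* No Richards/Brody or four-parameter growth families; no per-animal
  mixed-effects curves.
* No TMM/median-of-ratios normalization or batch correction; the NB test
  assumes library-size scaling is sufficient.
* Seed matching ignores hybridization energy and site context; the
  permutation null calibrates counts, not affinities.
* The cis window is a proximity proxy, not a regulatory claim; GO/KEGG
  enrichment of target lists requires external databases and is out of
  scope.
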