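---
title: "Methods: models, hit rules, and design choices in zebratox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, hit rules, and design choices in zebratox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zebratox)
```

zebratox analyzes high-throughput embryonic zebrafish chemical screens in
which each 96-well plate carries one chemical at seven nominal concentrations
(0, 0.01, 0.1, 1, 10, 50, 100 µM; one plate row, n = 12 embryos, per
concentration; the 0 µM row is the in-plate vehicle control). Four data
domains are analyzed and then integrated: binary morphology endpoints,
embryonic photomotor response (EPR) at 24 hpf, larval photomotor response
(LPR) at 120 hpf, and an RNA-seq summary. This vignette documents the models,
the statistical hit rules, the synthetic-data generator, and the places where
the design was genuinely open and a choice had to be made.

## Morphology: incidence model and benchmark concentration

Each endpoint is scored present/absent per embryo, aggregated into
per-concentration incidence counts. Wells dead at an endpoint's scoring stage
are excluded from the denominator of non-mortality endpoints; mortality is
its own endpoint over all wells, which avoids double counting. The
consolidated **Any Effect** endpoint is the logical OR over the 120-hpf
abnormality endpoints (mortality never feeds it).

The dose–response model is a three-parameter log-logistic with upper
asymptote 1, fitted by binomial maximum likelihood:

$$p(c) = p_0 + (1 - p_0)\,\frac{c^h}{c^h + \mathrm{EC}_{50}^h}, \qquad p(0)=p_0 .$$

This is the simplest monotone binomial model consistent with a
benchmark-response analysis; the fit is pluggable behind
`fit_dose_response()`. Optimization is bounded quasi-Newton (L-BFGS-B) on
$(\operatorname{logit} p_0, \log \mathrm{EC}_{50}, \log h)$ from a fixed
3×3×3 start grid, keeping the best optimum — deterministic, invariant to row
order, with an honest `converged` flag. The Hill fraction is evaluated as
$\operatorname{plogis}(h(\log c - \log \mathrm{EC}_{50}))$, which is
overflow-safe for extreme slopes.

The benchmark concentration uses **added risk**: the BMC at benchmark
response BMR solves $p(\mathrm{BMC}) - p_0 = \mathrm{BMR}$, implementing "a
10% higher response than the negative control" literally (BMR = 0.10 by
default, i.e. a BMD10). Closed form:

$$\mathrm{BMC} = \mathrm{EC}_{50}\left(\frac{q}{1-q}\right)^{1/h},
\qquad q = \frac{\mathrm{BMR}}{1-p_0},$$

verified at every call against a bisection root of the fitted curve to
10⁻⁶ relative. Note the BMC is increasing in both EC50 and BMR — a larger
benchmark response is reached at a larger concentration. Two degenerate
situations raise a classed error rather than returning a number: an
unattainable response ($1 - p_0 \le \mathrm{BMR}$) and a fit whose BMC lands
more than 100× above the highest tested concentration (the all-zero-incidence
case, where no finite potency is demanded by the data). No confidence limits
(BMDL/BMDU) are computed, and there is no model averaging.

Two significance rules coexist deliberately:

* **LEL** (lowest effect level): one-sided *exact binomial* test per non-zero
  concentration against the control rate, α = 0.05. A control incidence of 0
  makes the exact test degenerate, so the null rate is floored at
  $0.5/n_\mathrm{control}$ (configurable). The LEL is the lowest significant
  tested concentration.
* **Fisher activity flags**: one-sided Fisher's exact test per concentration
  with family-wise control implemented as Bonferroni across the non-zero
  concentrations of the endpoint (0.05/6 at the standard design).
  "Family-wise error rate" names a goal, not a procedure; Bonferroni is the
  transparent choice and is exactly reproduced by a hypergeometric
  enumeration oracle in the tests.

## EPR: interval summaries and the compound hit rule

The 51-s assay is 30 s darkness, a 1-s light pulse, 9 s darkness, a second
1-s pulse, 10 s darkness. Per-frame movement indices are summarized as means
over three half-open windows anchored at assay start: background [21, 30) s,
excitatory [31, 39) s, refractory [41, 48) s. Half-open windows avoid double
counting; a frame exactly at t = 30 s belongs to the pulse, not the
background.

A concentration is active in an interval iff **both**:

1. the two-sample Kolmogorov–Smirnov test comparing *per-embryo interval
   means* (treated vs in-plate control) has p < 0.007 — the Bonferroni
   correction 0.05/7 over the concentration groups; and
2. the relative peak difference of the *across-embryo mean trace* within that
   interval's window is ≥ 50 %:
   $|\max m_T - \max m_C| / \max m_C \ge 0.5$.

KS is applied to per-embryo means because animals, not frames, are the
independent units; peaks are taken per interval window because the 50 % rule
is a trace-level notion and an interval-resolved peak is the most local
reading of it (whether the original screen used per-interval or global peaks
is not determinable; this choice is configurable in effect through the
windows). The D statistic is the exact supremum ECDF gap; the p-value is the
asymptotic two-sample Kolmogorov tail
$Q(t) = 2\sum_{k\ge1}(-1)^{k-1}e^{-2k^2t^2}$ at
$t = \sqrt{n_x n_y/(n_x+n_y)}\,D$. Arms with fewer than 3 embryos after
excluding wells dead at 24 hpf are reported `untestable`, never "inactive".
Hit calls are invariant to common positive rescaling of all movement indices
and to animal order.

## LPR: binning, AUC, and the activity rule

The 24-min assay is four 3-min-light / 3-min-dark cycles; movement sampled
every 40 ms is integrated into 6-s bins (150 samples per bin; binning
conserves total distance exactly). The first cycle is acclimation. The
protocol text "only the 3rd light/dark cycle was analyzed" is ambiguous once
the acclimation cycle is excluded: the default here is the third *analyzed*
cycle (overall cycle 4), configurable to overall cycle 3 via
`lpr_protocol(analysis_cycle = 3)`.

Per larva, AUC is the sum of bin distances over both epochs of the analysis
cycle; larvae dead or malformed at 120 hpf are excluded first. The published
activity rule "p < 0.01 and the AUC treatment:control ratio ≥ 1.0 or ≤ −0.3"
cannot be a literal ratio of non-negative AUCs (a ratio is never negative),
so it is implemented as the signed relative change
$\mathrm{rel} = (\bar A_T - \bar A_C)/\bar A_C$, with hyperactivity at
rel ≥ +1.0 and hypoactivity at rel ≤ −0.3, KS p < 0.01 on the per-larva
AUCs. Both thresholds are configurable through `hit_thresholds()`.

## Behavioral benchmark concentrations

Screens report behavioral BMDs without a published recipe for converting a
continuous response into a benchmark-able incidence. The rule here is an
explicit editorial choice: a treated animal is "affected" when its summary
response (EPR interval mean, or LPR AUC) falls outside the control empirical
[2.5th, 97.5th] percentile interval; the resulting incidence table (controls
classified against their own interval, so the background sits near 5 %)
feeds the same log-logistic fit and added-risk BMC. At the null,
approximately 5 % are affected everywhere and the 10 % added-risk response is
usually unattainable, which is the desired behavior.

## RNA-seq summary

The transcriptomic design pools all control replicates into a single
**global control** (the standard screen design is 10 exposures × 4 replicate
pools + 8 control pools = 48 samples, 8 embryos per pool), used both as the
normalization reference and as the comparison arm for every exposure.

* **Normalization**: median-of-ratios size factors (median over all-positive
  genes of the sample count over the gene's geometric-mean reference).
* **DE test**: an engine-agnostic stand-in, documented as such — per gene, a
  negative binomial model (variance $\mu + \alpha\mu^2$) with
  method-of-moments dispersion pooled across arms (floored at 0, i.e.
  Poisson), and a Wald statistic on the log2 fold-change of group means
  referred to a t distribution on $n_1+n_2-2$ df — the small-sample reference
  that absorbs the noise of the plug-in variance. Externally produced
  per-gene tables (`deresults.tsv`) are ingested by `read_deresults()` and
  everything downstream is engine-agnostic.
* **DEG definition**: raw p ≤ 0.05, inclusive, no fold-change cutoff and no
  multiplicity adjustment — deliberately broad and exploratory, exactly as
  screens of this kind define it; users should treat DEG counts as a signal
  magnitude, not an error-controlled discovery list.
* **Overlaps**: exclusive-intersection (UpSet) counts; the combination counts
  partition the union by construction.
* **PCA**: variance stabilization approximated by
  $\log_2(\mathrm{count}/\mathrm{sf} + 1)$, restricted to the 500 most
  variable genes (both configurable), centered SVD.
* **Enrichment**: upper-tail hypergeometric test per gene set with
  Benjamini–Hochberg adjustment across sets; enriched pathways roll up to
  top-level functional classes (count and mean −log10 p per class).

## ToxPi integration

Each slice is one data domain. The default slice sources are an editorial
choice (the original screen's exact slice inputs are not printed): the
potency-transformed benchmark concentration for morphology, EPR and LPR,
DEG counts for RNA-seq, and descriptor columns for the physicochemical
domain. The potency axis is $-\log_{10}(\mathrm{BMC}/\mu M)$; any strictly
decreasing transform gives the same min–max-scaled ordering, −log10 is
chosen for interpretability. Slices are min–max scaled across the chemical
set (`invert` flips direction); a constant slice scales to all 0; an
inactive endpoint (no BMC) is a sentinel that always scales to 0 — absence
of detectable potency is the weakest signal. Multi-column domains are
averaged after per-column scaling. The score is the weighted mean
$\sum w_j s_j / \sum w_j$ with equal weights by default, so scores live in
[0, 1]; ranking is total, with ties broken lexicographically by chemical id.

**Ward clustering** of profiles is an own implementation of agglomerative
Ward linkage via the Lance–Williams update on squared Euclidean distances,
with exact ties broken by the lexicographically smallest creation-ordered
cluster pair, so merge trees are identical across platforms. Heights are the
within-cluster variance increase ΔSS (`stats::hclust(method = "ward.D2")`
heights equal $\sqrt{2\,\Delta SS}$); tests verify equality against a
from-scratch criterion oracle for n ≤ 6 and against `hclust` on larger random
matrices. Missing profile values are a hard error directing to imputation —
silent imputation inside a clustering routine hides decisions.

## The synthetic-data generator

The generator defines the study conditions under which every claim about the
pipeline is tested; it emulates the screen's design, not any particular
chemical:

* Plates at the standard design (7 concentrations, n = 12, one chemical per
  plate); per-endpoint Bernoulli scoring from the same log-logistic family
  the fitter assumes, with background incidence p0 ∈ [0, 0.05), EC50
  log-uniform in [0.5, 60] µM (inside the tested range), Hill slope in
  [1, 3]; mortality draws set the well status flags.
* EPR traces: strictly positive lognormal baseline (mean 0.5, CV 0.6) plus a
  decaying-exponential burst (amplitude 3, τ = 2 s) after each pulse, the
  refractory burst attenuated to 35 % — the screen literature describes no
  generative model, so any positive-amplitude burst shape satisfying the
  interval contrasts is acceptable; exposure multiplies burst amplitudes by
  a Hill-shaped effect curve with eff(0) = 1.
* LPR bins: multiplicative unit-mean lognormal noise (CV 0.5) around
  light/dark epoch means 4/12 per 6-s bin, scaled by the chemical's effect
  curve; zero noise gives exactly the expected rates.
* Counts: gene-wise NB with variance $\mu + \alpha\mu^2$, α log-uniform in
  [0.01, 0.3], baseline means log-uniform in [20, 500], lognormal size
  factors (log-SD 0.2); a stated fraction of genes gets true log2
  fold-changes ~ Normal(0, lfc_sd).
* One master seed threads hierarchically: each (chemical, assay) pair hashes
  to its own child stream, so adding a chemical never perturbs the draws of
  the others.

What passing tests on these data do **not** show: real screens have
plate/clutch effects, non-log-logistic dose–responses, autocorrelated
behavior traces, count outliers and batch structure, none of which the
generator emulates. The validation studies certify the pipeline's internal
correctness and its operating characteristics under its own model class.

## Validation studies and problem sizes

Three study functions back the package's quantitative claims (they are what
`scripts/acceptance.R` runs):

* `study_bmc_recovery()` — 100 active chemicals at the standard design,
  scored on a compact four-endpoint catalog (mortality at both stages plus
  two abnormalities; the per-endpoint estimation problem is unchanged and the
  study stays inexpensive); reports per-pair |log10(BMC_est) −
  log10(BMC_true)| for every estimable pair, with a documented target median
  ≤ 0.5 log10 units.
* `study_null_hit_rates()` — 500 null chemicals; EPR traces simulated at
  5 frames/s (the hit rule consumes interval means and window peaks, which
  are insensitive to frame rate); reports observed EPR per-interval, LPR,
  and family-wise Fisher false-positive rates against their nominal levels
  (0.007, 0.01, 0.05). The compound rules are conservative by construction.
* `study_de_calibration()` — 5000 null genes (4 vs 8 pooled-control
  replicates) for p-value uniformity, and 300 genes with an exact planted
  4-fold change at dispersion 0.01 for power.

## Known limitations

* The dose–response family is fixed (log-logistic, upper asymptote 1); no
  BMDL/BMDU, no model averaging.
* The DE stand-in has no dispersion shrinkage or independent filtering; with
  2–4 replicates per arm its power profile differs from moderated engines.
* Behavioral BMCs depend on the percentile-classification rule; other
  conversions (e.g. effect-size thresholds) would give different values.
* The asymptotic KS p-value is an approximation at n = 12; it is used
  inside conservative compound rules, and the type-I study measures the
  realized level.
* Descriptors are ingested, never computed from structure; only substituent
  counts are derived.
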