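---
title: "Methods behind crowdaffect: reliability and quality of crowdsourced affect ratings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind crowdaffect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdaffect)
```

## The problem

Normative affect datasets label pictures on the Self-Assessment Manikin
(SAM) scales — valence, arousal and dominance, each a 9-point integer
scale — using small groups of raters in controlled lab settings.
Crowdsourcing offers a cheaper route to such labels, but raises two
questions this package quantifies on any ratings table:

1. **Reliability** — if the same campaign were run again with k ratings per
   picture, how similar would the aggregated labels be?  How large must k
   be before labels stabilize?
2. **Quality** — how close do aggregated crowd labels come to gold
   normative values, and are there systematic shifts?

Alongside these, the package characterizes the *shape* of per-picture
rating distributions: polarizing content produces bimodal distributions
that a mean and SD summarize poorly, and polarized opinions tend to
persist across pictures of a common theme.

## Intraclass correlations

Reliability and quality are both intraclass correlations from the two-way
random-effects, single-measurement family.  For an $n \times k$
items-by-raters matrix, the crossed ANOVA decomposition without
replicates gives mean squares $MS_R$ (rows/items), $MS_C$
(columns/raters) and $MS_E$ (residual), computed exactly from row, column
and grand means (`anova_mean_squares()`; validated against a brute-force
decomposition and R's `aov()`).

* **Consistency**, ICC(C,1):
  $\dfrac{MS_R - MS_E}{MS_R + (k-1)\,MS_E}$ — additive shifts between
  raters do not count against it; it measures whether raters order and
  space the items the same way.
* **Absolute agreement**, ICC(A,1):
  $\dfrac{MS_R - MS_E}{MS_R + (k-1)\,MS_E + \frac{k}{n}(MS_C - MS_E)}$ —
  systematic shifts enter through $MS_C$ and lower the coefficient.

Consistency is used for across-run reliability; agreement for the
crowd-versus-gold comparison, where a crowd that rates everything one
point higher than the lab should not score perfectly.  Single-measurement
forms are used throughout; average-measure forms are out of scope, as are
confidence intervals and F-tests.  Missing cells are handled by
complete-case row deletion (with the dropped count reported) — imputation
is deliberately not offered at this layer.

Qualitative bands follow the conventional reading: ICC ≥ .75 *excellent*,
≥ .4 *fair*, below *poor* (`interpret_icc()`, thresholds configurable).

Two regime caveats, verified in the test suite: a column shift leaves
$MS_R$ and $MS_E$ exactly unchanged, so consistency is exactly
shift-invariant; but "shifts never increase agreement" holds only when the
shift moves a column *away* from the grand mean and the matrix has a
genuine item effect ($MS_R > MS_E$).  Likewise ICC(A,1) ≤ ICC(C,1) only
when $MS_C \ge MS_E$.  Both coefficients are reported side by side partly
for this reason.

## The dip statistic and modality calls

The dip of a sample is the smallest sup-norm distance between its
empirical CDF and the class of unimodal (convex-then-concave)
distribution functions; large dips indicate multimodality.  Ties are
treated as infinitesimally separated order statistics — the convention of
the classical index-based algorithm — which implies
$\text{dip} \ge 1/(2n)$ for every sample, with equality for perfectly
unimodal configurations, and $\text{dip} = 1/2$ for a single point.

**Computation.**  The sample is collapsed to distinct values
$v_1 < \dots < v_K$ with cumulative proportions $p_t$.  Placing the mode
at $v_k$, a unimodal CDF within a band of half-width $d$ around the ECDF
exists iff a nondecreasing *convex* chain through the bands
$[p_t - d,\, p_{t-1} + d]$ reaches the mode from the left at some value
$a \in [p_{k-1} \pm d]$, a nondecreasing *concave* chain leaves it on the
right from some $b \in [p_k \pm d]$, and $a \le b$ (the mode's atom is
climbed between $a$ and $b$).  Mode-in-gap placements are limits of the
adjacent mode-at-value placements.  Chain feasibility is decided exactly
by propagating the reachable set in the (value, slope) plane, a convex
polygon under the three per-step operations (upward slope relaxation,
shear by the spacing, band clipping); the implementation (compiled code)
stores slopes as rises over the traversed gap so all coordinates stay
O(1).  The dip is then found by bisection over $d$ (40 halvings of a
0.25-wide bracket, resolving far below 1e-9), with the lower bound
$1/(2n)$ returned exactly when feasible.  The test suite checks the
implementation against an independent exact linear-programming
minimization over the same CDF class on thousands of samples.

**Calibration.**  P-values come from Monte-Carlo sampling of the null
dip distribution under the uniform distribution — the asymptotically
least favourable unimodal null — rather than interpolation tables: 2000
replicates by default, with the add-one estimator
$p = (1 + \#\{d^\ast \ge d\})/(R+1)$ so p-values are never zero.  Null
tables depend only on the sample size and are cached per
(n, replicates, seed); `modality_summary()` shares one table across
pictures of equal pool size while keeping jitter seeds per picture.

**Ties and jitter.**  Ratings on a 9-point scale are heavily tied.  The
default tie policy adds uniform jitter in (−0.5, 0.5) under a derived
seed before computing the dip — the usual remedy for scale data — with a
`raw` mode available; both are exercised in tests.  The unimodal versus
multimodal call compares the Monte-Carlo p-value to α = 0.05 by default
(the conventional level; the package classifies by p-value rather than by
raw dip magnitude).

**Power.**  The dip is a conservative test.  Measured on two-cluster
normal mixtures at n = 40 with a 2000-replicate null: centers 4 SD units
apart give power ≈ 0.4–0.5, rising to ≈ 0.95 at 5 SD and ≈ 1 at 5.7 SD.
Detection of polarized pictures therefore requires subgroup separation
comfortably above the within-subgroup spread; this drives the generator's
default noise level (below) and bounds what modality fractions mean on
noisier real data.

## Reliability from simulated runs

A *crowdsourcing run* of size k draws, for each picture, k ratings
uniformly without replacement from that picture's pool, independently
across runs (runs overlap — a pool of 30–50 ratings cannot support 30
disjoint runs of up to 15).  The across-run reliability at k is the
consistency ICC of the pictures × runs matrix of run means; the curve
over k = 1..15 with 30 runs per size, and its first crossing of a
threshold, yield the minimum-ratings recommendation
(`reliability_curve()`, `min_ratings()`).  Per rating size the curve
reports the mean and SD of the ICC over 10 independently seeded run-set
replicates — the dispersion bands one would plot.

The default sampling unit is ratings-per-picture: whole-worker sampling
cannot guarantee exact per-picture counts under page-structured coverage,
though a `per_run_workers` mode exists for sensitivity analysis.

Under an additive homoscedastic model (picture variance $\sigma_P^2$,
rating variance $\sigma_W^2$) the curve converges to the closed form
$\sigma_P^2 / (\sigma_P^2 + \sigma_W^2 / k)$ as pool and run counts grow
(`analytic_icc()`).  At finite pool size P the ICC is inflated by the
without-replacement correction $(P-k)/(P-1)$ on the within-variance term
— run means drawn from the same finite pool correlate through it.  The
validation suite uses the continuous `make_additive_pool()` (no rounding,
so planted components are exact): the closed form is verified within
±0.05 at pool 50 over k ∈ {1,2,3,5,8,15} with 200 pictures, and
minimum-ratings recovery uses 1500 pictures with pool 500, where a
delta-method power analysis puts the per-seed misclassification
probability of the planted crossing (within-variance 0.9× the picture
variance crossing .75 at k = 3; 2.5× at k = 8) at a few percent.

## The synthetic generator

No crowd SAM dataset is publicly deposited, so every stage is validated
against a generator that emulates the statistical structure of such a
campaign (`generator_config()`, `generate_crowd()`).  A rating by worker
w on picture p is

$$ r_{wp} = \mathrm{round}\big(\mathrm{clip}(\mu_p + s_{w,\theta(p)}\,\delta
   + b_w + \varepsilon,\; 1, 9)\big), \qquad
   \varepsilon \sim N\!\big(0,\; \sigma(\mu_p)\, m_{\mathrm{pop}}\big) $$

with round-half-even rounding, and
$\sigma(\mu) = \sigma_{\min} + (\sigma_{\max} - \sigma_{\min})
(1 - |\mu - 5|/4)$: residual noise peaks at the neutral midpoint of the
scale and shrinks toward the extremes, reproducing the SD-versus-
extremity profile crowdsourced affect data shows.  Defaults and
rationale:

| parameter | default | why |
|---|---|---|
| pictures / page size | 60 / 20 | a typical normative picture set, annotated in whole pages (workers take 1–3 pages) |
| ratings per picture | 30–50 per population | the pool size a week-long two-population campaign accumulates |
| populations | specialized ×1.0, general ×1.3 | a reputable, costlier tier and a noisier general tier; the multiplier gap is a modelling choice, not a measured value |
| unimodal means | U(2, 8) | normative means rarely sit at the scale ends; keeps clipping ≈ 3% (< 5%) |
| σ_min, σ_max | 0.35, 0.55 | residual within-subgroup noise; chosen so the planted δ = 2 subgroup separation is ≈ 5σ after bias/jitter/rounding inflation and hence detectable by the dip at n = 40 |
| rater bias SD | 0.3 | mild per-worker additive style differences |
| multimodal fraction / δ / themes | 0.25 / 2 / 3 | a quarter of pictures polarized into subgroups at μ ± 2; membership signs persist per worker across each theme's pictures |
| polarized centres | U(3.5, 6.5) | polarizing content sits near neutral and keeps μ ± δ on scale |
| gold reference | 200 simulated raters, separate stream | gold labels are themselves finite-sample means, like lab norms from small rater groups |

Two independent seed streams (crowd versus gold reference, plus
fixed-label derived streams per stage) make every artifact reproducible
bit for bit from one master seed.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: real residual SDs on polarized affect items run
1.5–2 scale points, well above the defaults here, so dip power on real
campaigns is lower than in these tests; worker fatigue, response times,
picture semantics, and demographically structured (rather than random)
subgroup membership are all absent; clipping at the scale ends is rare by
construction.  The generator defines the *structure* the pipeline must
recover, not the noise level of any particular platform.

## Opinion transfer

For a pair of pictures, ratings of the workers who rated both are
binarized around the neutral value 5: below → 0, above → 1, exactly
neutral → excluded (the transform defines only "below" and "above";
neutral ratings are counted and reported rather than assigned a side).
`transfer_counts()` reports n00, n11, n_change and n_excluded, which
always partition the common raters.  Across all pairs of dip-flagged
multimodal pictures, a lower switch fraction within same-theme pairs than
across themes is the signature of opinions persisting over thematically
related content; the generator's theme structure reproduces it and the
suite verifies it in ≥ 95% of replicate campaigns.

## Quality against gold labels

Crowd labels aggregate simulated runs at k = 8 ratings per picture by
default — matching the rater counts behind typical normative values —
via the grand mean of sampled ratings (`aggregate_crowd()`).  Agreement
with gold is the absolute-agreement ICC of the pictures × 2
(crowd, gold) matrix; per-picture deviations ≥ 1.5 scale points
(configurable) are flagged and sorted.  Systematic shifts are tested by a
paired two-sided t-test of crowd versus gold means per dimension
(a Wilcoxon signed-rank alternative is surfaced in the output metadata),
Bonferroni-corrected across the dimensions tested — the family size is
the number of dimensions analyzed, which is logged, since larger implicit
families would change corrected p-values.

## Numerical choices and problem sizes

* Dip bisection: bracket [1/(2n), 0.2500001], 40 halvings; clip/hull
  tolerance 1e-12 on O(1)-conditioned coordinates; agreement with the
  exact-LP oracle is asserted at 1e-9.
* ICC decomposition in closed form from means; oracle agreement asserted
  at 1e-10 over 500 random matrices up to 10 × 6.
* Rounding of generated ratings: R's round-half-even, stated and stable.
* Seeds: every stochastic stage derives an integer stream from the master
  seed and a fixed label (below 2^31), so stage results are independent
  of execution order; RNG state is saved and restored around internal use.
* Validation sizes: 1000 samples for dip-oracle equivalence and for null
  calibration (n = 40, 2000 replicates); 20 replicate campaigns for
  modality-fraction recovery; 50 seeds per planted-variance regime for
  minimum-ratings recovery; 30 campaigns for theme persistence.

## Known limitations

* The dip's conservatism: moderate bimodality (≈ 4σ separation) is
  detected only about half the time at n = 40; reported unimodal
  fractions are upper-bound-ish on noisy data.
* Finite-pool inflation of across-run ICCs (the $(P-k)/(P-1)$ factor) is
  inherent to subsampling one pool; recommendations at k far below the
  pool size are barely affected, but curves at k near the pool size
  overstate the reliability of a fresh campaign.
* The Bonferroni family is the set of dimensions analyzed; other
  correction scopes must be applied by the caller.
* No ICC confidence intervals; the dispersion column of the reliability
  curve is a run-set replicate SD, not a sampling-theory interval.
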