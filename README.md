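# crowdaffect

Tools for deciding whether — and under what configuration — crowdsourcing
yields reliable, high-quality emotion labels for pictures rated on the
Self-Assessment Manikin (SAM) scales: valence, arousal and dominance, each
on a 9-point integer scale.  It is written for researchers running or
auditing affect-annotation campaigns who need to answer: *how many ratings
per picture are enough*, *how close do crowd labels come to lab-collected
normative (gold) values*, and *which pictures polarize raters into
persistent opinion subgroups*.

## What it computes

**Reliability.** Crowdsourcing runs of k ratings per picture are simulated
by subsampling each picture's rating pool (30 runs per k, k = 1..15 by
default). The reliability at k is the two-way random-effects,
single-measurement *consistency* intraclass correlation of the
pictures × runs matrix of run means,

    ICC(C,1) = (MS_R − MS_E) / (MS_R + (k−1) MS_E),

from an exact crossed-ANOVA mean-squares decomposition. The smallest k
whose ICC reaches a band threshold (≥ .75 excellent, ≥ .4 fair) is the
minimum-ratings recommendation.

**Quality.** Crowd labels aggregated at k = 8 ratings per picture are
compared with gold labels through the *absolute agreement* form,

    ICC(A,1) = (MS_R − MS_E) / (MS_R + (k−1) MS_E + (k/n)(MS_C − MS_E)),

which, unlike consistency, penalizes systematic shifts; per-picture
deviations are flagged, and a Bonferroni-corrected paired t-test checks for
mean shifts per dimension.

**Rating-distribution shape.** Per picture, Hartigan's dip statistic — the
minimum sup-norm distance between the empirical CDF and the class of
unimodal (convex-then-concave) distribution functions, computed here by an
exact band-feasibility construction with Monte-Carlo calibration against
the uniform null — classifies the rating distribution as unimodal or
multimodal. A binarized opinion-transfer analysis (below/above the neutral
value 5) then measures whether polarized raters keep their side across
thematically related pictures.

**Synthetic campaigns.** Because crowd SAM datasets are rarely deposited, a
generator reproduces the statistical structure of such campaigns (pages of
20 pictures, two worker populations of different noise tiers, 30–50
ratings per picture, noise peaking at the neutral midpoint, a quarter of
pictures with two latent opinion subgroups persisting across themes) with
bit-reproducible output, so the entire pipeline is testable end to end.

## Worked example

```r
library(crowdaffect)

syn  <- generate_crowd(generator_config(seed = 42))   # ratings + truth + gold
pool <- pivot_matrix(syn$ratings, "valence", "specialized")

curve <- reliability_curve(pool, sim_config(k_range = 1:10, seed = 42))
head(curve, 5)
#>   k   icc  icc_sd n_runs      band
#> 1 1 0.658 0.01212     30      fair
#> 2 2 0.796 0.00401     30 excellent
#> 3 3 0.855 0.00682     30 excellent
#> 4 4 0.892 0.00677     30 excellent
#> 5 5 0.916 0.00320     30 excellent
min_ratings(curve, 0.75)
#> [1] 2

crowd <- aggregate_crowd(pool, k = 8, n_runs = 30, seed = 42)
agreement_with_gold(crowd, syn$gold, "valence")
#> ICC(A,1, single rater) = 0.9759  [excellent]
#>   n = 60 subjects, k = 2 raters (0 rows dropped)

modality_summary(syn$ratings, "valence", "specialized", seed = 42)$fraction_unimodal
#> [1] 0.7666667
classify_modality(pool["pic004", ], seed = 42)
#> dip = 0.0957, p = 0.0055 (n = 38, 2000 replicates, jitter ties) -> multimodal
```

Reading the numbers: with one rating per picture the campaign is only
fairly reliable (ICC .66); two ratings already cross the .75 excellent
band under this generator's noise level, so `min_ratings()` recommends 2.
Aggregated 8-rating crowd means agree with the gold labels at ICC(A,1)
= .98. About 77% of pictures have unimodal rating distributions —
pic004, one of the planted polarized pictures, is correctly called
multimodal (dip .096, Monte-Carlo p ≈ .006).

The same pipeline runs from the shell via
`Rscript inst/scripts/crowdaffect.R simulate|analyze ...`, writing a
consolidated `report.json` plus per-stage CSVs.

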