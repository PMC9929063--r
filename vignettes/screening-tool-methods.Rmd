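---
title: "Deriving and applying stepwise obstetric social-support screening tools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and applying stepwise obstetric social-support screening tools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(obscreen)
```

## The problem and the data model

Antenatal care offers repeated contact with essentially all pregnant women,
which makes the obstetric visit a natural place to detect the few percent
who need social support coordinated with a public health center. The raw
signal is a short structured interview sheet per care period (14 items at
the first visit, 11 in the second trimester, 8 in the third, 7 postpartum,
counting the EPDS row). Every item has a non-risk ("positive") and a risk
("negative") answer set; `encode_record()` maps answers to binary risk
indicators, matched case-insensitively after trimming because the printed
answer sets capitalise inconsistently. Missingness is a first-class third
state: nothing is imputed at the data layer, and each downstream stage
states its own handling.

One deliberate deviation from the printed sheet: the maternal-age row lists
"<25" on the non-risk side, but every use of the variable treats age
under 25 as the risk factor (its crude odds ratio is about 15 in that
direction), so the packaged schema codes "<25" as risk. Similarly, the
number-of-children item uses "three or more" as the risk side.

A *cohort* is a data frame of one record per woman — indicators, the binary
outcome `admin_cooperation` (needed public-health-center cooperation),
`hospital_support`, and the postpartum EPDS total — tagged with its period
and provenance.

## The derivation pipeline

`derive_tool()` chains the stages below; each is also exported on its own.

**Dual regression.** The derivation needs two column families that no
single model produces: standardized partial regression coefficients (SPRCs)
for scoring, and odds ratios with confidence intervals for reporting. We
therefore pair an ordinary least-squares fit on variance-standardized
columns (`fit_linear_standardized()`; the outcome is standardized too by
default, with a switch, since coefficients scale trivially either way) with
a maximum-likelihood logistic fit (`fit_logistic()`, IRLS, tolerance 1e-10,
at most 100 iterations; 95% Wald intervals with the 1.96 multiplier, the
convention of mainstream commercial statistics packages). Both use
complete-case (listwise) deletion and report the n actually used. Complete
separation — a zero cell in a term's 2×2 margin, or an exploding standard
error — is flagged per term rather than raised, because rare exposures such
as illegal drug use routinely separate in cohorts of a few hundred.

**Item exclusion.** An item whose crude and adjusted associations point in
opposite directions (`exclude_sign_reversals()`) is dropped: the adjusted
sign is confounding-driven and unusable as a risk weight. Estimates exactly
at the null have no direction and are kept. Items that mandate referral
regardless of score (drug use) are configured out of scoring but kept as
short-circuit triggers. The retained items enter **one** adjusted refit;
scores are read from that single fit and never refit per exclusion, so
removing one item can never silently change another item's points. If a
negative coefficient survives into that single fit (possible in noisy
cohorts), the item is dropped from the scoring table with the reason
recorded, without a further refit.

**Scoring.** A retained item's points are its SPRC × 100 rounded *half-up*
(`round_half_up()`), not banker's rounding — the printed reference tables
round 13.5 to 14 and 16.5 to 17. The rounding mode is per-period
configuration: the packaged first-visit tool keeps one decimal, the
second-trimester tool whole points, reproducing the published tables from
their coefficients.

**Cutoff.** `roc_curve()` places operating points at every distinct
attained total score under the screening convention "positive iff
score ≥ t" (thresholds are attained values, not midpoints, because a
deployed paper form needs a quotable cutoff) and computes AUC as the
Mann-Whitney rank statistic with ties counting one half; the suite
cross-checks it against both exhaustive concordant-pair counting and an
independent ROC implementation. `select_cutoff()` maximizes the Youden
index, breaking ties toward the lower (more sensitive) threshold — the
published sensitivity/specificity pairs (0.92/0.92 and 0.82/0.62) are
consistent with sensitivity-plus-specificity maximization, and the
criterion is an enum so alternatives can be added. A candidate tool is
accepted iff its AUC reaches `min_auc = 0.70`, boundary inclusive: the
published derivations accept at 0.77 and reject at 0.46 without naming a
bound, and 0.70 is the conventional floor between "poor" and "acceptable"
discrimination that separates those two outcomes.

**Narrowing rules.** STEP-2 selects items by prevalence among
outcome-positive women at a 0.30 threshold, *inclusive* at the boundary
(an item at exactly 30% among ten outcome-positives is selected; the
alternative strict reading is a flag). Candidates include items excluded
from scoring. The second-trimester variant computes each item's Spearman
correlation with the outcome within the score-positive group — item versus
outcome, not item versus total score, the reading consistent with selecting
"higher-risk" factors — weights it by 10 and keeps items reaching 2 points
(ρ ≥ 0.2), skipping zero-variance items with a warning. STEP-3 item sets
and the minimum count are configuration: no data-driven selection rule is
defined for them, so the packaged tools carry the published sets (first
visit: at least 2 of depression symptoms, maternal mental disorder,
consultation request; second trimester: at least 1 of no talking with
partner, partner violence, depression symptoms, consultation request).

**Step semantics.** The default is sequential narrowing — each step filters
the previous step's positives — which is the only reading consistent with
the published funnels (54 → 20 → 14 and 110 → 21 → 12). A `union` mode
(any single step's criterion flags the record) exists behind a flag because
the prose describing the steps is ambiguous.

## Applying a frozen tool

`apply_tool()` evaluates one record: mandatory-referral items first, then
the three steps. At screening time a *missing* indicator contributes 0
points and does not satisfy step rules — the screen-negative direction —
because a deployable screen must handle partially completed forms; the
count of missing scored items is carried on the result. Complete-case
deletion applies only at model fitting. `screen_cohort()` aggregates a
funnel report; percentages are rounded half-up to whole percents (the
one-decimal variant is an argument), matching the reporting style of the
reference counts, which ship as a packaged fixture (`paper_counts()`).

Screening invariants, property-tested over a thousand random records per
period: flipping any item to risk never lowers the total score nor demotes
the stage; positives ⊆ STEP-2 survivors ⊆ STEP-1 survivors; stage labels
partition the screened cohort.

## The EPDS association analysis

`epds_association()` binarizes the postpartum EPDS total at ≥ 9 (the
community-validated Japanese cutoff for suspected postpartum depression;
the instrument's own 10-item scoring is out of scope — the total is an
input), excludes items with fewer than 5 risk-positive records
(`min_exposed = 5` is the smallest bound consistent with every published
exclusion, which dropped items with 1–4 exposed), then reports crude odds
ratios from univariate fits and adjusted odds ratios from one multivariable
fit entering all kept items of the period together.

## The synthetic-cohort generator

No cohort is deposited, so `generate_cohort()` emulates the structure the
analysis assumes: the outcome is Bernoulli at the period's prevalence
(0.025 first visit, 0.06 second trimester, matching the published
need-for-support proportions), and each indicator is drawn conditionally
independently given the outcome with odds(p₁) = OR × odds(p₀), so every
item's 2×2 odds ratio equals its generating value in expectation.
Generating odds ratios default to the published crude estimates;
conditional independence is the simplest structure consistent with the
published variance inflation factors, which sit near 1. Baseline
prevalences p₀ are published nowhere; the packaged defaults are
field-plausible values chosen once so that simulated STEP-1 positive rates
land broadly near the published ones (about 8% simulated vs 9.7% at the
first visit, 22.5% vs 22.8% in the second trimester) and are labelled
approximate in the defaults file. `generate_epds()` draws EPDS ≥ 9 from a
logistic model in the indicators (effect odds ratios defaulting to the
published adjusted estimates) whose intercept is calibrated by bisection to
the target marginal prevalence of 6.7%, then fills an integer total
uniformly within the indicated band. `inject_missingness()` masks
indicator cells completely at random — only missing counts, not a
mechanism, are published — and never masks outcomes.

What passing tests on these cohorts do *not* show: behaviour under
inter-item correlation (real risk factors cluster), informative
missingness, longitudinal linkage of one woman across periods, or any
recovery of the original fitted coefficients, which would require the
original cohort.

## Numerical choices and problem sizes

Half-up rounding adds a one-ulp guard before flooring so that coefficients
stored in binary (0.165 × 100) still round as printed. The EPDS intercept
bisection runs to 1e-8 on [-50, 50] and errors when the target prevalence
is unattainable. Ties in the Youden index resolve to the lowest threshold;
ties in scores contribute half a concordance to AUC. Degenerate inputs
(one-class outcomes, zero-variance or aliased items, empty first-stage
subsets) raise named errors rather than propagating NaNs, except per-term
logistic separation, which is a flag.

The suite's statistical checks use sizes chosen to make their tolerances
comfortable multiples of the Monte-Carlo error at a fixed seed: odds-ratio
recovery within ±10–15% at n = 50,000–400,000 (larger where rare items make
the log-odds-ratio standard error largest), the EPDS marginal prevalence
within ±0.003 at n = 100,000, null-model interval coverage over 20
replicates of n = 5,000, and oracle-equivalence sweeps over hundreds of
random small instances.

## Known limitations

The packaged reference tools are transcriptions, not re-derivations: their
coefficients came from a cohort that is not available, and this package
cannot (and does not try to) reproduce them from data. The generator's
baseline prevalences are approximations, so simulated funnels resemble but
do not match the published stage counts. The third trimester ships only a
coefficient fixture documenting the rejected candidate (AUC 0.46); the
postpartum sheet has a schema but no tool, since none was derived from it.
Inter-period transitions of support status are not modelled.
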