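---
title: "Methods: sex-specific variability of blood parameters via CV ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-specific variability of blood parameters via CV ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question and the statistic

When both sexes are used in a mouse experiment, a sex that is systematically
more variable would need larger groups to reach the same power. `micecvr`
asks whether such a systematic difference exists in strain-survey blood
data: 25 clinical-chemical and hematological parameters measured across many
projects, strains and both sexes, as distributed by repositories in the
style of the Mouse Phenome Database (MPD).

The unit of analysis is the *strain data set*: the female and the male group
of one strain for one parameter within one project. For each group the
coefficient of variation is `CV = SD / mean`, and the two groups are
compared through the **CV ratio**

```
r = CV_f / (CV_f + CV_m)
```

`r = 0.5` means equal variability; `r > 0.5` means the females are more
variable. Unlike the plain quotient `CV_f / CV_m`, the ratio is bounded in
[0, 1], symmetric around 0.5 (`r(a, b) + r(b, a) = 1`), and cannot explode
when one CV is near zero. An external yardstick calibrates its scale: a 37%
difference in CV between two groups — the inflation reported for group
housing relative to single housing — corresponds to `r = 0.61` or `0.39`
depending on orientation. Observed mean ratios are judged against that
deviation.

## Selection and exclusion rules

Animals enter the analysis when (in this fixed order of rejection reasons):

1. their strain class is inbred, Collaborative-Cross-derived inbred,
   F1 hybrid or recombinant inbred (no engineered alleles);
2. they are untreated;
3. their age is within 7–26 weeks, **inclusive** on both ends, applied per
   animal: in a group with mixed ages every animal must qualify.

Groups are then summarized per (project, parameter, strain, sex) with the
sample SD (n − 1 denominator; the convention for reported phenotype SDs —
and since it is applied to both sexes alike, the CV ratio is invariant to
the choice). A strain data set is formed when both sexes are present with
at least `min_n_per_sex` animals (5 in the main analysis, 10 in the
replication). Because raising the threshold only removes data sets, the
n ≥ 10 pool is a subset of the n ≥ 5 pool by construction.

A data set is excluded as a high-variability outlier when the female and/or
the male group has CV **strictly** above 0.5; a CV of exactly 0.5 stays in.
The reason code (`female_cv` / `male_cv` / `both_cv`) preserves the
breakdown of which sex triggered the rule. The strain-family analysis runs
with this rule disabled. CVs are computed on the raw measurement scale (no
log transform), and a non-positive group mean invalidates the group rather
than producing a negative CV — every parameter in scope is strictly
positive biologically.

## Aggregation and tests

Per parameter and threshold, the summary row reports the **unweighted**
mean and sample SD of the CV ratios (each data set counts once, regardless
of group size — the analysis counts data sets, not mice), strict counts of
ratios above and below 0.5 with integer percentages (rounded half-up, as
printed summaries conventionally are), the ratio range, the total number of
mice and the number of contributing projects. A parameter with no surviving
data sets yields an explicit empty row. Ties at exactly 0.5 — possible with
integer-valued toy inputs, measure-zero in continuous data — count in
neither bucket and are excluded from the percentage denominator, but enter
mean, SD and range.

The counts above/below 0.5 are tested against an equal split with a
Pearson chi-squared test. For two cells with expected counts `(a + b) / 2`
the statistic collapses to the closed form `(a − b)^2 / (a + b)` on 1 df;
no continuity correction is applied (the classical Pearson form; the
package's tests confirm the significance pattern of the printed data-set
counts is insensitive to that choice at the decision level used here).
Alpha defaults to 0.05. No multiple-testing correction is applied across
the 25 parameters; the decision criterion is instead *consistency*: a
parameter counts as showing a robust imbalance only if the test rejects in
both the n ≥ 5 and the n ≥ 10 analysis.

Two further consistency flags guard interpretation:

* **mean vs proportion** — the mean ratio falls on the opposite side of 0.5
  from the majority of data sets (a skewness symptom); a mean exactly 0.5
  or equal counts flag nothing;
* **cross-threshold** — the mean ratio strictly changes side of 0.5 between
  the two analyses.

Formatting rule: ratios are printed to 2 decimals, except that a value
whose 2-decimal rounding would read "0.50" is printed to 3 decimals — which
side of 0.5 a mean falls on is the quantity of interest and must survive
printing. All flags are additionally written as explicit boolean columns,
never encoded in typography alone.

## Strain families

The strain-level view pools data sets by designation prefix into named
inbred families (defaults: A/J, BALB/c, C3H, C57BL/6, CBA — with the
trailing slash in the prefix so only true CBA/ substrains match — and
DBA/2J via the prefix `DBA/2`, pooling all DBA/2 substrains; the prefix is
configurable). Matching is case-sensitive and longest-prefix-wins, so a
config may carry both `C57BL/6` and `C57BL/6N` as distinct families. Per
family × parameter the mean ± SD of the ratios is reported (SD absent for
a single data set), with `gt_half` computed from the **unrounded** mean.
The overview counts, per family, the parameters with mean ratio above 0.5
among those with at least 5 (respectively at least 1) data sets.

## The synthetic generator

No per-animal source data are redistributable at desk scale, so validation
rests on a seeded generator of MPD-style cohorts with known ground truth
(`simulate_animals()`, with truth records written alongside so tests never
re-derive truth from the data). It emulates the *structure* the pipeline
consumes: multiple projects, strains drawn from a pool of real inbred
designations (so family assignment is exercised), two sexes per strain
data set, group sizes 5–30 (or fixed), ages inside or outside the 7–26
week window, an optional treated fraction, and per-sex target CVs with
`CV_f = k · CV_m`. Values are lognormal by default — blood analytes are
positive and right-skewed — with log-scale sigma `sqrt(ln(1 + CV^2))` and
the log-mean set so the arithmetic mean hits the target; a truncated
normal is available for sensitivity checks. The small-n downward bias of
the sample CV is deliberately not corrected (the analysis uses raw CVs);
the equal-CV null stays centered at 0.5 by symmetry regardless.

Outliers are injected per *data set* at rate `outlier_fraction`, with the
affected sex(es) drawn from an 11:6:6 female/male/both split mirroring the
breakdown observed in real strain surveys (about 1.1% female-only, 0.6%
male-only, 0.6% both, of 2.3% total). A design point worth recording: an
outlier group is *defined by its realized CV*. The group is redrawn (fresh
target CV from (0.5, 0.9] each attempt) until its empirical CV exceeds the
exclusion threshold. Drawing only the target CV above 0.5 would leave a
substantial fraction of "outliers" with empirical CV below the threshold
at small n (around 30% at n = 10, by simulation) — the injected truth
would then disagree with what the exclusion rule can see, and "fraction
excluded" would have no clean expected value. With the realized-CV
definition, injected truth and the rule's verdict coincide by
construction, and the excluded fraction is binomially distributed around
the injected rate.

What the generator does **not** emulate: estrous-cycle stage, housing
structure, litter effects, lab-to-lab unit differences (CVs are
scale-free), age-dependent means, or between-strain heterogeneity of the
true CV. Passing tests therefore show that the pipeline's arithmetic,
rules and calibration are correct under a faithful null and a known
alternative — not that any biological conclusion transfers to a particular
real survey snapshot.

## Validation conditions and numerical choices

The packaged checks run at these problem sizes, chosen as the smallest
scales at which the statistical claims are sharp:

* null calibration: 1000 pools of 100 data sets (10 animals/sex, CV 0.15
  both sexes); the equal-split test's empirical type-I error must stay at
  or below 7% at alpha 0.05 (the test is conservative-to-nominal on
  discrete counts of 100), and the fraction of ratios above 0.5 must lie
  inside the exact binomial 99% interval around 0.5;
* recovery: 500 data sets at 200 animals/sex; for `k = 1.37` the pooled
  mean ratio must land within 0.02 of `k/(1+k) = 0.578`, for `k = 1`
  within 0.01 of 0.5;
* exclusion: 2000 data sets (10–30 animals/sex) with 2.3% injected
  outliers; every retained data set must obey the rule and the excluded
  fraction must fall in the binomial 99% bounds of the injected rate.

Other numerical conventions: division by zero is never performed (a data
set with both CVs zero is dropped as degenerate before the ratio); the
chi-squared test with zero total count is reported not-evaluable rather
than NaN; percentages use half-up rounding; write-then-read round-trips
preserve doubles exactly (full-precision TSV).

## Limitations

The pipeline ingests files; it does not download from a live database, and
summary cell values of any particular repository snapshot drift over time,
so the packaged analyses demonstrate semantics and calibration on
synthetic cohorts rather than reproducing a snapshot. Strain-class labels
must be supplied by the caller (no nomenclature inference); multi-age
cohorts within one project are treated as prepared upstream; and
hematocrit, MCH and MCHC are out of scope as derived quantities.
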