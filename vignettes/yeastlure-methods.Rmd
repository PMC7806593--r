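---
title: "Statistical methods for yeast-volatile attraction assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for yeast-volatile attraction assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yeastlure)
```

## The experimental setting

Spotted-wing drosophila (*Drosophila suzukii*) and related species locate
fruit largely by the volatiles of the yeasts fermenting on it, which makes
yeast ferments candidate lures for monitoring and mass trapping. The data
structures this package analyses come from two assay types:

* **Two-choice T-maze runs.** A cohort of 60–80 flies is released into the
  central compartment of a T-maze whose arms carry a yeast-ferment
  treatment and a sterile-juice control. After a fixed time each fly is in
  the treatment arm, the control arm, or still in the centre. A large
  fraction (roughly 40–70%, depending on species) never leaves the
  centre.
* **Field traps in randomised blocks.** Each block contains one trap per
  bait treatment; trapped *D. suzukii* are counted by sex, and other
  drosophilids separately, per trap and session.

## Attraction Index and single-treatment inference

For an informative replicate (at least one fly chose an arm) the
Attraction Index is

$$AI = \frac{n_{\text{treatment}} - n_{\text{control}}}
            {n_{\text{treatment}} + n_{\text{control}}},$$

+1 for total attraction, −1 for total repulsion, 0 for indifference.
Replicates in which no fly left the centre carry no choice information and
are omitted from all attraction statistics by `filter_informative()`
(they still count toward retention). Treatments are displayed as the
unweighted mean ± SE of per-replicate AIs.

Whether a treatment departs from random choice is tested by an exact
binomial test on the *pooled* counts across replicates
(`binomial_choice_test()`): the summed treatment-arm count against the
summed choosing count at success probability ½. Pooling follows the
assays' design, where each replicate is a cohort of the same fly culture
run simultaneously across treatments. The two-sided p-value uses the
minimum-likelihood convention (sum of the probabilities of all outcomes
no more likely than the one observed), which at p = ½ equals doubling the
smaller tail capped at 1. Because each treatment's test asks only whether
that treatment differs from its own control, no multiple-testing
correction is applied across treatments; tests are two-sided by default
because repulsion is a real outcome (one-sided alternatives are available
through the configuration).

Differential attraction *across* treatments within a fly species is
tested by a binomial logistic regression at the replicate level with
treatment as the sole fixed factor, compared with the intercept-only
model by a deviance (likelihood-ratio) chi-square test
(`treatment_effect_test()`). Deviance reductions and degrees of freedom
are reported as positive magnitudes. The residual deviance/df ratio of
the treatment model is reported, and a ratio above 2 raises a warning
for between-replicate overdispersion; no quasi-likelihood adjustment is
applied automatically, so the warning is a flag, not a model change.

The joint effect of fly species and yeast treatment on AI is assessed by
a two-way ANOVA with interaction (`species_by_yeast_anova()`) using
type-II sums of squares, chosen because replicate numbers differ between
treatments and type-II main-effect tests do not depend on term order.
Central-compartment retention is compared across species with the same
binomial-logistic machinery on stay-versus-leave counts
(`retention_test()`).

## The additive null for blends

The package's core inferential question is whether a blend of volatiles
from separately fermented yeasts attracts more or less than expected if
the constituents combined additively. The null model is constructed by
permutation (`build_null()`): each draw selects, uniformly with
replacement across draws, one observed per-replicate AI for every
constituent isolate and averages them; 10,000 draws by default. The
observed statistic is the mean of the blend's per-replicate AIs, and the
two-sided p-value doubles the smaller empirical tail with an add-one
correction, \((\text{count}+1)/(N+1)\), so p is never exactly zero
(`permutation_pvalue()`). Design choices worth making explicit:

* *With-replacement sampling across draws.* Constituents have only ~6
  replicates each, so thousands of draws necessarily reuse values; within
  a draw exactly one value per constituent enters the mean.
* *Equal constituent weighting*, matching blends mixed in equal
  proportions post-ferment. The linear-model route exposes optional
  weights.
* *Order invariance.* Constituents are sorted by name before sampling, so
  the p-value is exactly invariant to the order in which a blend's
  constituents are listed.
* *Seeding.* All draws descend from one integer seed; identical inputs
  and seed give bit-identical p-values. The pipeline derives per-blend
  seeds from the run seed in sorted blend order.

A complementary parametric route (`lm_interaction_test()`) fits
per-replicate AI on treatment indicators across the blend and its
constituents and tests the contrast
\((\text{blend mean}) - (\text{mean of constituent means})\) against its
pooled-variance t reference. An equal-variance two-sample t-test
(`blend_vs_single_ttest()`) compares the best blend with the best single
isolate.

### Calibration properties, honestly stated

The permutation null compares a *mean of m blend replicates* against
draws that are *means of one replicate per constituent*. These two
quantities do not have the same sampling variance: with per-replicate AI
variance \(v\), \(c\) constituents and \(m\) replicates everywhere, the
observed statistic varies (around the additive truth) with
\(v/m + v/(c\,m)\), while the null draws spread with
\(\tfrac{m-1}{m}\, v/c\). The test is therefore conservative for blends
of few constituents and anticonservative for blends whose constituent
count is large relative to the replicate count; in the package's
simulated study conditions the type-I rate at α = 0.05 ranges from about
0.03 for two-constituent blends to well above 0.05 for a
twelve-constituent blend, with a panel-average close to the nominal
level. The test suite measures these rates; users comparing blends of
many constituents should prefer the linear-model contrast, whose
t reference accounts for all group sizes, or read small permutation
p-values for large blends with caution. A related granularity caveat:
with ~6 replicates per constituent the null has limited support, so
extremely small p-values (near \(1/N\)) reflect the observed mean falling
outside the resampled range rather than a precisely estimated tail.

## Field-trap inference

Per-trap *D. suzukii* totals are compared across baits with a
tie-corrected Kruskal–Wallis test (`kruskal_wallis()`; mid-ranks, H
referred to chi-square on k − 1 df) followed by Dunn's pairwise
comparisons (`dunn_posthoc()`) using mean-rank differences with the
tie-corrected variance and Benjamini–Hochberg adjustment across all
pairs. Compact letters are assigned by the standard insert-and-absorb
procedure, so two baits share a letter exactly when their adjusted
p-value is ≥ α. Tie correction matters here because field tables contain
many tied zero counts.

In parallel, the sex-split counts are modelled at the trap × sex grain by
a log-link Poisson GLM, `count ~ treatment + sex + block`
(`fit_trap_glm()`). The assay description of a "random block effect
inside a GLM" is internally inconsistent; the package defaults to block
as a fixed factor — in this balanced design the treatment contrasts are
essentially identical — and offers `random_block = TRUE` for a
random-intercept Poisson mixed model via lme4. The treatment effect is a
deviance test against the no-treatment model. Per-treatment estimated
marginal means average over sex and block *on the link scale* before
back-transforming (the emmeans convention) with 95% Wald intervals, and
an overlap grouping (numbers) is built with the same insert-and-absorb
procedure on the CI-overlap relation. The Pearson χ²/df overdispersion
ratio is always reported; no automatic quasi-Poisson switch is made. The
pipeline can repeat the whole analysis with the positive-control lure
removed, and marks a pairwise difference "consensus-significant" only
when the Dunn and CI-overlap routes agree.

## The synthetic-data generator

Every stage is testable end to end without external data through seeded
generators whose defaults emulate the assays' structure:

* `simulate_tmaze()`: each fly independently stays in the centre with
  probability *r* and otherwise picks the treatment arm with probability
  \((1 + a)/2\), so `E[n_centre] = n·r` and the conditional expected AI
  is *a*. Cohort sizes are uniform on 60–80 unless fixed.
* `simulate_blend_study()`: a blend's true AI is the mean of its
  constituents' true AIs plus an interaction offset δ, clamped into
  \([-1, 1]\) with a message when clamping triggers.
* `simulate_field()`: counts for treatment t, block b, sex s are Poisson
  with mean \(m_t f_s e^{u_b}\), \(u_b \sim N(0, \sigma_b^2)\); realised
  block effects are attached for parameter-recovery checks.

Three presets fix the study conditions used throughout the tests.
`simulate_lab_single()`: twelve isolates and a juice-vs-juice control
across three fly species, with attractive isolates at AI 0.36–0.06
(species-specific profiles, including one repulsive isolate at −0.20 for
one species), retention 0.69/0.42/0.62, mostly 6 replicates with 18 for
two retested isolates and 9 for the control. `simulate_lab_blend()`: one
species, 6 replicates, retention 0.69, ten blends of 2–12 constituents,
additive except the five-isolate and twelve-isolate blends at
δ = −0.25 and −0.20 — the chosen emulation of blends markedly less
attractive than their additive prediction. `simulate_field_single()`:
eight baits in six blocks with per-trap expected totals 10 (water) to
237 (best yeast), the commercial lure at 500 (well ahead of every yeast,
as positive controls are), block SD 0.3 on the log scale, 55% females.

What the generator deliberately does **not** emulate: between-replicate
(cohort) overdispersion in choice probabilities, any coupling between
retention and attraction (a hook exists but defaults off), temporal or
spatial structure beyond the block effect, and species composition of
non-target captures. Passing calibration on these synthetics therefore
shows the inferential machinery is correct under the stated generative
model, not that real cohorts are free of extra-binomial variation — the
overdispersion diagnostics exist precisely because real data may not be.

## Numerical choices and degenerate inputs

* Counts must be non-negative integers; fractional values are rejected,
  never rounded.
* An all-constant AI table short-circuits the ANOVA to F = 0, p = 1
  rather than a 0/0 failure; an all-tied Kruskal–Wallis input reports
  H = 0, p = 1.
* A zero-pooled-variance t-test returns t = 0, p = 1 when means are equal
  and errors otherwise; a zero-residual linear-model contrast returns
  p = 1 when the contrast is exactly zero.
* All-zero treatments in the Poisson GLM are warned about and their lower
  CI bound reported as 0.
* Complete separation in the binomial logistic regression (a treatment
  with all-or-none pooled choices) warns but still returns the deviance
  of the fitted proportion limit.
* Problem sizes used by the package's own verification: exact-oracle
  scans to n = 200 trials; enumeration oracles up to 3 constituents × 4
  replicates; 1,000 simulated data sets for each type-I calibration; 500
  for power; 10,000 permutation draws throughout.

## Known limitations

The permutation additivity test's size depends on the
constituent-to-replicate ratio as described above. The Wald intervals
behind the marginal-mean grouping ignore overdispersion, so with Pearson
χ²/df well above 1 the grouping is anti-conservative; the reported ratio
should gate interpretation. Dunn's test relies on the large-sample normal
approximation of rank differences, which is crude below ~5 observations
per group. The pipeline treats each trap × session record as one
observation and does not model repeated sessions of the same trap
position.
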