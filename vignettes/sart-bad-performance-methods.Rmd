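---
title: "Methods: longitudinal SART bad-performance analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal SART bad-performance analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The task and the statistic

The Sustained Attention to Response Task (SART) presents the digits 1–9 in
fixed order, 23 times over, for 207 presentations per session. The
participant presses a key for every digit except 3 (the no-go digit).
Two kinds of mistake exist: a *commission* (pressing on a 3) and an
*omission* (failing to press on a go digit). Word of caution on
terminology: "trial" is used in the field both for a single digit
presentation and for one 9-digit pass. This package calls the former a
**presentation** and the latter a **cycle**; only that reading makes the
0–23 range of the statistic below coherent.

The central derived variable is the **bad performance (BP)** count: the
number of cycles in which the participant committed at least 4 of 9
possible mistakes. BP is a burst detector — it responds to short collapses
of attention that session-level means dilute. Alongside BP the package
computes total mistakes, mistakes in *good* cycles (those with at most 3
mistakes; the threshold is strict, a 3-mistake cycle is good), and the
mean and SD of reaction time. RT summaries are taken over *responded*
presentations only — go hits and commission presses — because unresponded
presentations carry no RT; whether commission presses should be included
is genuinely ambiguous in the field, so it is the documented default
rather than a hidden choice.

## Trajectory clustering

Participants assessed at two waves (four years apart) are represented as
points \((BP_1, BP_3)\). Fuzzy c-means (FCM) partitions these points
softly: each participant receives membership probabilities per cluster,
updated by the standard Bezdek iteration

$$u_{ik} = \frac{1}{\sum_j (d_{ik}/d_{jk})^{2/(m-1)}}, \qquad
  q_i = \frac{\sum_k u_{ik}^m x_k}{\sum_k u_{ik}^m},$$

with hard assignment by maximum membership (ties to the lowest index).
Defaults: fuzzifier \(m = 2\) (the universal FCM default; exposed as a
parameter), tolerance \(10^{-6}\) on the maximum membership change, at most
1000 iterations, 5 seeded restarts keeping the lowest objective. Points are
used untransformed: BP counts at the two waves share a scale, so no
standardisation is applied.

The cluster count is chosen by an elbow scan of the within-clusters sum of
squares,

$$WSS(c) = \sum_{i=1}^{c}\sum_{x \in C_i}
  \left[(x_{w1}-q_{i,w1})^2 + (x_{w3}-q_{i,w3})^2\right],$$

computed on hardened partitions (the formula sums over crisp sets) for
\(c = 1, \dots, 10\). The verbal elbow rule — "the first point of the
minimum" — is not operational, so the package automates it as follows,
a choice made on first principles rather than fitted to any outcome:

* successive drops are normalised by the total dispersion,
  \(g_c = (WSS(c-1) - WSS(c)) / WSS(1)\). Raw successive ratios never
  flatten on structureless data (splitting any blob keeps removing a
  roughly constant *fraction* of its internal variance), whereas drops
  relative to total dispersion reproduce the classical scree reading;
* the suggested \(c\) is the smallest whose next gain \(g_{c+1}\) falls
  below a knee ratio (default 0.15), **and** whose smallest hard cluster
  holds at least `min_cluster_size` members (default 5) — a solution with
  an excessively small cluster is rejected even when the knee rule likes
  it, mirroring how such solutions preclude meaningful statistics;
* when the data form a single tight clump — \(WSS(1)/n < 1\) in squared BP
  units, an absolute criterion that is natural for an integer-valued
  statistic — one cluster is suggested outright.

The scan table is always emitted so a human can overrule the suggestion.

For a three-cluster solution the clusters receive semantic colours from
their centroid geometry: **blue** is the centroid with the smallest
\(BP_1 + BP_3\) (healthy/stable), **red** the largest \(BP_3\) among the
rest (decliners), **green** the remainder (typically improvers).

## Decline definitions and cluster characterisation

Clinical decline between waves is defined per variable:

| variable | decline rule | units |
|---|---|---|
| TUG | wave 1 < 12 and wave 3 ≥ 12 | s |
| UGS, DTGS | wave 1 ≥ 100 and wave 3 < 100 | cm/s |
| MMSE, MoCA | drop of ≥ 2 points | points (0–30) |
| falls | 0 before wave 1, > 0 before wave 3 | count |

A flag is *absent* (NA), never FALSE, when either wave's value is missing.
Characterisation runs at three levels: (i) paired Wilcoxon signed-rank
tests of each variable between waves within each cluster (the
related-samples test is the appropriate one for paired waves, and is used
throughout even where rank-sum language sometimes appears in this
literature); (ii) Mann-Whitney U tests comparing the relative inter-wave
change \((x_1 - x_3)/x_1\) between cluster pairs (undefined at \(x_1 = 0\);
such cases are excluded with a reported count); and (iii) Pearson
chi-square tests (no Yates correction) of decline proportion against
cluster membership — for a 2 × 3 table df = 2 and the 5% critical value is
5.99. An expected count below 5 triggers a warning rather than an
automatic exact test. Note that a relative change of −5.82 corresponds to
a 582% increase (the end/start *ratio* is 6.82); the package reports the
formula value. The orientation of each variable ("higher is better" for
gait speeds and cognitive scores, the reverse for TUG and falls) is
explicit configuration, not inference. No multiple-testing correction is
applied, matching standard practice for this descriptive characterisation.

## Predicting future bad performances

The binary outcome — any bad performance at the later wave — is modelled
by four nested logistic regressions per candidate predictor (wave-1 BP,
total mistakes, or mistakes in good cycles; never co-entered): tier 1 the
predictor alone; tier 2 adds mean and SD RT; tier 3 adds age, sex,
education; tier 4 the fully adjusted model (anxiety, depression,
anti-hypertensives, diabetes, smoking, drinking, baseline gait speed,
physical activity). Reference levels are primary/none education, never
smoker, drinking "no", low IPAQ. Fits use IRLS via `glm`; reported ORs are
exponentiated coefficients with Wald 95% intervals \(e^{\beta \pm 1.96
SE}\) and Wald p-values (likelihood-ratio tests are not emitted, matching
the convention of the software this analysis style comes from). Predictors
are screened for multicollinearity with pairwise Spearman correlations;
the failure threshold defaults to \(|\rho| > 0.7\) and is configurable —
observed field values around 0.42 are reports, not rules. Quasi-complete
separation fails loudly, listwise deletion is applied per model and the n
used is reported.

## The synthetic cohort generator

Real two-wave SART cohort data of this kind is access-restricted, so the
package ships a generator that makes every stage testable. It is a
first-class, tested module, not a fixture. Each participant is drawn into
one of three latent trajectory classes (defaults: 94% stable, 5%
improving, 1% declining). A session is generated per wave as a *per-cycle
lapse mixture*: each cycle lapses with a class- and wave-specific rate;
within a lapsed cycle every action goes wrong with high probability
(default 0.70–0.75), within a normal cycle with low probability
(0.02–0.03). This mixture — rather than i.i.d. per-presentation errors —
is what makes ≥4-mistake bursts occur at realistic rates, which is exactly
the structure BP detects. RTs are drawn from a normal truncated below at
150 ms (observed minima in published cohorts sit just above that); no RT
autocorrelation or post-error slowing is modelled, since the dynamics of
RT around errors are not characterised well enough to simulate honestly.

Covariates are class-conditional Gaussians (Poisson for falls), with
wave-3 values generated as wave-1 value + class shift + noise, rounded and
clamped for the 0–30 cognitive scores. Baseline means and SDs follow
published per-cluster descriptives; the decliner shifts (TUG +2.5 s, gait
speeds −25 cm/s, MMSE/MoCA −2.5 points, falls rate 0.3 → 0.8) are chosen
so that decliners preferentially cross the clinical cut-offs — the
"dramatic decline" phenotype. All defaults live in a versioned YAML file
(`inst/extdata/default_profiles.yaml`).

Seeding: one master seed; per-participant streams are derived by fixed
offsets, so enlarging a cohort never reshuffles earlier participants, and
every output is byte-reproducible.

What the generator does **not** emulate: the joint covariate distribution
of any real cohort (no survey weights, no realistic correlations between,
say, education and gait speed), item-level cognitive scores, practice
effects, or RT dynamics. Passing tests therefore demonstrate that the
pipeline's machinery is correct and calibrated under a plausible
three-class world — not that real cohorts contain exactly three classes.

## Numerical choices

* Printed percentages round half away from zero (one decimal for table
  changes), because that is how the summary tables this output style
  follows are formatted; `round()`'s banker's rounding would print 20.4
  where 20.5 is expected.
* Percent change from a zero baseline is reported as undefined, never as
  infinity.
* FCM membership ties in hard assignment, and coincident centroids in
  semantic labelling, break deterministically toward the lowest index,
  with a warning in the latter case.
* A point coinciding with a centroid receives a crisp membership.
* The FCM objective is asserted non-increasing in tests at a tolerance of
  1e-8 (floating-point slack on an analytically monotone quantity).

## Problem sizes used by the test-suite

The suite exercises the pipeline at sizes chosen to keep the statistics
honest while remaining quick to run: protocol and feature oracles at
single-session scale; law-of-large-numbers checks at 3000–5000 sessions
with 3-standard-error bands; cluster recovery and the elbow suggestion on
the default cohort at n = 1000 (adjusted Rand index ≥ 0.80 against the
true classes); the red-cluster decline property over 50 seeded cohort
replicates; logistic CI coverage over 200 replicates at n = 5000; and
chi-square null calibration over 2000 replicates with cluster sizes
800/150/50 and a 25% decline rate (sizes chosen so every expected count
stays above 5, where the asymptotic test is trustworthy).

## Limitations

* The elbow automation is a heuristic; on data without clear structure
  the scan table, not the suggestion, is the product.
* Wald intervals misbehave near separation; the package refuses such fits
  rather than reporting fragile numbers (no Firth/penalised fallback).
* The chi-square decline test is asymptotic; very small clusters warn but
  do not switch to an exact test.
* Figures are validated through their render manifests (spot counts,
  participant sets, conservation identities), not pixels.
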