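---
title: "Forensic analysis of p-value distributions: models and design choices"
author: "pexcess maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forensic analysis of p-value distributions: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pexcess)
```

## The problem

A literature's collection of reported p-values carries a signature of how
its studies were run. Under honest testing of a true null hypothesis,
p-values are uniform; under true effects the distribution of significant
p-values decreases monotonically in p. Questionable research practices
(QRPs) that chase significance distort this shape in two distinguishable
ways:

* a **bump** — a local excess just below .05 that makes the density
  non-monotonic, detectable by the Caliper test; and
* **monotonic excess** — inflated frequency below .05 while the density
  still decreases, invisible to the Caliper test and only detectable by
  comparing the observed distribution with one implied by a fitted
  effect-size model.

`pexcess` implements the full chain needed to look for both: parsing and
recalculating APA-reported results, the Caliper test and its time trend, a
simulator of the canonical bump-producing QRP (data peeking / optional
stopping), a chi-square estimator of the effect-size distribution from
truncated significant p-values, and two excess measures built on it — the
effect-size drop and the D odds ratio. A synthetic-corpus generator with
ground-truth labels makes every step testable end to end without access to
any real journal corpus.

## Reported results and their recalculation

`parse_apa_result()` recognises `t(df)`, `F(df1, df2)`, `r(df)`,
chi-squared (Greek and ASCII spellings, with or without `N = n`) and `Z`
results followed by `p = / < / >` or `ns`, recording the operator and the
number of reported decimals. Recalculation (`recalculate_p()`) is
two-tailed for t, r (via \(t = r\sqrt{df}/\sqrt{1-r^2}\)) and Z, and
upper-tailed for F and chi-squared; this matches how APA results are
conventionally reported. One-tailed reported tests are not modelled — a
reported one-tailed p will simply appear (gross-)inconsistent, which is the
transparent behaviour for a forensic tool.

`consistency_check()` accepts an exactly reported p when the recalculated
value lies within half a unit in the last reported decimal,
\([p - 5\cdot10^{-k-1},\ p + 5\cdot10^{-k-1})\); the `wide_05` policy
widens this to the closed interval \([.045, .055]\) for p reported exactly
as .05, the allowance used when asking how much misreporting survives even
generous rounding assumptions. A *gross* inconsistency additionally flips
significance at .05 between the reported and recalculated value; `p > x`
reports are read as claims of nonsignificance. Impossible records
(`F(0, 55)`, `|r| > 1`, nonpositive df) are removed before any analysis by
`filter_impossible()`.

## The Caliper test

`caliper_test()` compares counts in two narrow intervals below .05. Since
any mixture of true effects yields a non-increasing density of p, the
proportion `Pr` in the interval nearest .05 cannot exceed .5; the one-sided
exact binomial tail \(P(X \ge x \mid N, 1/2)\) tests for a bump. Interval
endpoints are half-open `[lo, hi)` internally. For *recalculated* p-values
the bins are adjacent (`[.0475, .04875)` and `[.04875, .05)` at the default
binwidth); for *reported* p-values, which cluster on the two-decimal grid,
the lower bin is shifted down to end at the gridpoint .04 (closed on the
right) and .05 itself is excluded, so that a two-decimal report lands
unambiguously. The boundary conventions only matter for values exactly on
a reporting gridpoint — a measure-zero event for recalculated p-values.

Binwidth trades power for sensitivity: wider bins include more p-values but
dilute the bump, because with true effects the underlying density falls
across the window. `bump_trend()` fits unweighted OLS of \(Pr - .5\) on
centered year, so the intercept is the bump size at the first year of data
collection and a positive slope means a growing bump; years with no
p-values in the window are dropped.

## The data-peeking simulator

`peeking_design()` describes the canonical optional-stopping protocol:
two groups of \(n_k = 24\), pooled-variance two-sample t-test; if the
first look is nonsignificant at \(\alpha = .05\), add
`round(n_k/3)` = 8 observations per group and retest the *accumulated*
data, up to three rounds (so the final look has 48 per group). The study's
true effect is drawn once as \(d \sim N(\delta, \tau)\). A condition run
(`simulate_condition()`) collects studies until a fixed number with final
p below .1 have been retained.

Two implementation points deserve emphasis:

* **Sufficient-statistic simulation.** `simulate_studies()` draws each
  batch's mean (\(\sim N(\mu, 1/m)\)) and centered sum of squares
  (\(\sim \chi^2_{m-1}\)) and pools them with the exact two-sample pooling
  identity, so look-to-look dependence is identical to raw-data
  accumulation; `simulate_study()` is the raw-data reference
  implementation and the test suite verifies the pooling identity exactly
  against `t.test()`.
* **Sidedness.** The stored (and stopped-on) p-value is one-tailed in the
  direction of the true effect by default (`alternative = "greater"`).
  This choice is empirical: only under one-tailed storage does the
  simulator reproduce the tabulated per-condition counts of the published
  simulation study of this protocol (the shares of retained studies below
  .05 and below .00125 match to the third decimal across the homogeneous
  conditions,
  and the D statistic of the null peeking condition lands at 2.0 rather
  than 2.15). `alternative = "two.sided"` is available and is what the
  synthetic corpus uses, since published APA results are two-tailed.

At the default settings, peeking inflates the null significance rate from
.05 to about .107 and produces its excess almost entirely in (.00125, .05]:
the mass below .00125 changes by under 2%, which is the premise that makes
the small-p fit below a credible estimate of the uncontaminated effect
distribution.

## The Fisher-z effect model

For the model-fit pool (t, r, and F with one numerator df), each result is
mapped to a correlation (\(r = t/\sqrt{t^2 + df}\), \(t = \sqrt{F}\)), then
to Fisher z with sampling standard deviation \(1/\sqrt{N-3}\), effective
\(N = df + 2\). True effects are modelled as
\(\rho_F \sim N(\delta, \tau^2)\), so an observed z is
\(N(\delta, \tau^2 + sd_z^2)\), restricted to positive observed effects.
The observed records keep their *exact* recalculated p-values; the normal
approximation enters only on the model side. This approximation (including
the effective-N mapping) is this package's own reconstruction of the fit —
the original technical appendix it descends from is not public — so small
systematic offsets against published simulation values are expected and are
reported rather than absorbed.

`fit_effect_model()` bins p over the fit range (40 equal-width bins over
0–1, 0–.05 or 0–.00125) and minimises Pearson's chi-square between
observed and expected counts; expected bin probabilities are closed-form
normal masses, averaged over the records' \(sd_z\) values and renormalised
over the range. The optimiser is a coarse grid (\(\delta\) step .01,
\(\tau\) step .005) with two tenfold local refinements.

**The ridge, and how ties are resolved.** On truncated ranges the
chi-square surface has a near-flat ridge: increasing \(\delta\) while
decreasing \(\tau\) leaves the conditional shape almost unchanged. At any
realistic sample size the chi-square differences along the ridge are far
smaller than sampling noise, so a machine-precision argmin would be decided
by the draw. The estimator therefore treats all evaluated points within
**one chi-square unit** of the minimum as ties and resolves them to the
smallest \(\tau\) (taking the best-fitting \(\delta\) at that \(\tau\)).
This makes ridge fits deterministic and reproduces the qualitative
behaviour of the published study of this protocol, whose peeking-condition
fits uniformly rest at \(\hat\tau = 0\). Fits on well-identified surfaces (the 0–1 range,
parameter-recovery settings) are unaffected because their one-unit region
is tiny. The reported misfit is the chi-square at the returned estimate.
Consequences worth knowing: under genuine heterogeneity with a small mean
effect, the truncated fit still sits on a ridge — the model *family*, not
the optimiser, is unidentified there — and quantities derived from the
fitted parameters (notably D) inherit that instability. This is precisely
the documented failure mode of D under heterogeneity.

## The two excess measures

From the pool of significant records (p ≤ .05):

* **Effect-size drop** = \(\hat\delta_{p\le.00125} - \hat\delta_{p\le.05}\).
  QRPs that pile up just-significant p-values drag the full-range estimate
  down but barely touch the small-p estimate, so a large positive drop is
  suspicious.
* **D odds ratio** = observed odds that a significant p lies in
  (.00125, .05] divided by the model-expected odds under the small-p fit.
  D > 1 signals excess just-significant results. The orientation is chosen
  so that the null peeking condition yields D ≈ 2 (matching the published
  arithmetic for that condition: observed share .0128 below the cut against the uniform .025),
  and injecting extra p-values into (.00125, .05] strictly increases D.

`true_D_from_labels()` computes, from the simulator's ground-truth labels,
the factor by which peeking actually inflated the interval — the benchmark
against which estimated D can be judged. `expected_significant_share()`
gives the model-implied fraction of significant results for a set of
records' degrees of freedom.

## The synthetic corpus

`generate_corpus()` emulates the statistical structure of a large extracted
psychology corpus: articles spread over journals and years, a mixture of
null, medium and large effects on the d scale, test families in roughly the
proportions seen in extracted corpora (t .45, F .30, r .10, chi-squared
.10, Z .05), 73% inexactly reported p-values, two reported decimals before
2010 and three after, and two injectable QRPs — data peeking at the
generative layer (t-machinery families only) and incorrect rounding at the
reporting layer (p recalculable in (.05, .055] reported as "= .05" or
"< .05"). Honest records report the p implied by their *reported* (rounded)
statistic, so a QRP-free corpus contains no gross inconsistencies by
construction; the "< .05" rounding QRP is always grossly inconsistent,
while the "= .05" variant is numerically correct rounding and is invisible
to any window-based check — an intrinsic limit of consistency checking,
not a defect of the detector. Ground truth lives in `truth_*` side columns
that no analysis function reads.

What the generator does *not* emulate: journal-specific reporting quirks,
one-tailed reports, table-only results, correlated results within an
article, and QRPs other than peeking and incorrect rounding. Passing tests
on synthetic corpora therefore demonstrate correctness of the machinery,
not field-realism of any particular prevalence estimate.

## Numerical and design choices

* Exact binomial tails everywhere in the Caliper test (no normal
  approximation), at every N.
* Bins and intervals are half-open `[lo, hi)`; fit-range membership is
  `(lo, hi]` on p, matching the "p ≤ cut" reading of truncation.
* Expected counts below 1e-8 flag their bins rather than trigger merging;
  with the large-n use cases merging would change the estimand.
* The chi-square grid spans \(\delta \in [0, 1.5]\), \(\tau \in [0, .6]\)
  (Fisher-z units), wide enough for any plausible psychology effect;
  `delta` is constrained nonnegative because only positive observed
  effects are fitted.
* Simulation scale: the packaged checks retain 1,000,000 studies with
  p < .1 per condition — the stopping rule of the published study of this
  protocol — which
  the sufficient-statistic simulator completes in roughly a minute per
  condition. Fits on the 0–1 range use all simulated studies (a pool
  truncated at p < .1 cannot populate 36 of the 40 bins); the retained
  count is used as the sample-size accounting.
* A single integer seed determines a condition's entire output stream.

## Known limitations

* The Fisher-z normal approximation and the effective-N mapping are a
  reconstruction; absolute values of chi-square misfit are not comparable
  across other implementations of the same idea.
* D is unreliable under effect heterogeneity (the ridge); the effect-size
  drop is the more robust of the two measures, and both are diagnostic
  signals rather than estimates of QRP prevalence.
* The parser deliberately covers the standard APA grammar only; results
  in tables or nonstandard formats are out of scope.
* Normal true-effect distributions are an idealisation; real literatures
  mix manipulation checks, main effects and controls, which violates the
  single-normal assumption for any real corpus.
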