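---
title: "Benchmark-dose modelling and cross-tissue comparison of genetic toxicology endpoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmark-dose modelling and cross-tissue comparison of genetic toxicology endpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmdrank)
```

## The problem

Multi-endpoint genetic toxicology studies measure, in the same animals, a
cascade of mechanistically linked quantities: covalent DNA adducts (exposure
to the activated genotoxicant), gene mutations (lacZ transgene mutant
frequency in any tissue, Pig-a mutant phenotype frequency in blood), and
chromosomal damage (micronucleated reticulocytes and erythrocytes).
Comparing the potency of a compound across tissues and across these
endpoints requires a dose metric that does not depend on which dose groups
happened to be tested.  The benchmark dose (BMD) is that metric: the dose
at which the fitted mean response reaches a pre-specified benchmark response
(BMR) above background.  `bmdrank` implements the full quantitative pipeline
of such a study: dose-response modelling, BMD estimation with
profile-likelihood confidence intervals, trend testing, confidence-interval
ranking across tissues, cross-endpoint comparison, and a proportionality
analysis between endpoint BMDs.

## The dose-response model family

Responses are strictly positive, so errors are taken log-normal:
`log y ~ Normal(log f(x), sigma^2)`, with a single residual `sigma` shared
across dose groups of a dataset.  The mean curve `f` comes from the nested
exponential family customarily used for continuous dose-response data in
regulatory benchmark-dose work:

| id | form | parameters |
|----|------|------------|
| m1 | `a` | 1 |
| m2 | `a exp(b x)` | 2 |
| m3 | `a exp(b x^d)` | 3 |
| m4 | `a (c - (c - 1) exp(-b x))` | 3 |
| m5 | `a (c - (c - 1) exp(-b x^d))` | 4 |

Every member satisfies `f(0) = a` (the vehicle-control background); `m4`
and `m5` saturate at `a * c`, so `c` is the maximum response expressed as a
multiple of background.  The shape exponent is restricted to `d` in
`[1, 4]`: the lower bound prevents infinite slope at dose zero (and the
wildly unstable low-dose extrapolation that comes with it), the upper bound
is the conventional cap for this family.  For the saturating members the
increasing orientation is enforced (`b > 0`, `c > 1`).  For `m2`/`m3` the
sign of `b` is left free while fitting: this makes the first
model-selection step a two-sided test of "any dose effect", with type-I
error equal to its nominal level; a fitted decreasing trend is then
reported as a flagged no-BMD result rather than inverted.

The BMR is parameterized as CES, the fractional increase over background;
`ces = 1` (a two-fold increase, "BMD(100)") is the default used for
genotoxicity endpoints, because a doubling tends to lie inside the observed
response range of all endpoints.  The BMD has closed forms, e.g.
`log(1 + ces)/b` for `m2` and `-(1/b) log((c - 1 - ces)/(c - 1))` for `m4`;
for `m4`/`m5` the benchmark response is reachable only when `c > 1 + ces`,
and the error message carries the offending asymptote.

## Fitting and model selection

The log-likelihood is concentrated analytically in two directions:
`log a` is a location parameter on the log scale, and the profiled `sigma`
is the root-mean-square log residual (floored at `1e-6` so that noiseless
data keep a finite likelihood).  The numerical search therefore runs over
one to three transformed parameters only (`log b`, `log(c - 1)`, a scaled
logit of `d`), with `m2` reducing to ordinary least squares and `m3` to a
1-d profile over `d`.  For `m4`/`m5` the search is multi-start: a
moment-based heuristic, the solution of the nested simpler model (which
guarantees a monotone likelihood ladder up to optimizer tolerance), and ten
Latin-hypercube draws over a bounded box in the transformed parameters,
drawn under a fixed seed so that fits are deterministic.  Nelder-Mead runs
that exhaust their iteration budget on the flat `c`-ridge that these
likelihoods develop under weak saturation are restarted from their own
endpoint before being declared unconverged.

Model selection follows the nested likelihood-ratio ladder: `m2` vs `m1`
(df = 1; if not significant, the no-effect model is selected); then `m3` vs
`m2` and `m4` vs `m2` (df = 1 each), carrying the better-supported accepted
candidate with ties resolved towards the saturating `m4`; then `m5` vs the
carried model (df = 1).  A step is accepted when twice the log-likelihood
gain exceeds `qchisq(0.95, df)` (3.841 for df = 1).  One extension to this
topology proved necessary: when *neither* three-parameter model passes its
df = 1 step, `m5` is tested directly against `m2` with df = 2 (critical
value 5.991).  Superlinear-and-saturating dose-responses -- a late steep
onset levelling off near the top dose, exactly the pattern of the
insensitive tissues in this kind of study -- are invisible to either single
added parameter but decisively favoured when shape and asymptote enter
jointly; without the rescue step such datasets were systematically
mis-assigned to `m2`, with badly biased BMDs.  The full ladder trace
(statistics, degrees of freedom, critical values, decisions) is kept in the
selection object and serialized with it.

Note one property the family does *not* have: `m5` nests `m4` (`d = 1`)
and `m2`/`m3` nest `m1`, but `m5` does not nest `m3` at finite parameters
(its large-`c` limit is linear, not exponential, in `x^d`).  On strongly
convex data that never saturate, `loglik(m5) < loglik(m3)` can therefore
occur legitimately; the ladder handles this by simply not accepting the
step.

## Profile-likelihood confidence intervals

The BMDL and BMDU are the two-sided 90% profile-likelihood bounds: the
selected model is reparameterized so the BMD is an explicit parameter
(`b` is expressed in terms of the BMD and the remaining parameters), all
nuisance parameters are maximized out at each fixed BMD, and the bounds
solve `2 (LL_max - LL_profile(BMD)) = qchisq(0.90, 1) = 2.7055`.  Roots are
located by doubling-bracket expansion away from the MLE followed by Brent
root finding on the log-dose scale.  Numerically, the nuisance optimization
reuses the same concentrated structure as fitting: closed-form `log a` and
`sigma`, a 1-d grid-plus-golden-section profile over `log(c - 1 - ces)`
(the optimum can sit arbitrarily close to the `c = 1 + ces` boundary,
where the curve degenerates into a step to exactly the benchmark level),
and for `m5` an outer 1-d profile over `d`.  The upper search is capped at
100 times the top dose; a profile that never crosses the cutoff below the
cap yields a capped BMDU with an explicit `bmdu_unbounded` flag.  Estimates
carry the precision ratio BMDU/BMDL and the geometric midpoint
`sqrt(BMDL * BMDU)` used for ranking.  A selected `m1` (or a decreasing
trend) produces a result object with a reason, not an exception, so
pipelines over many datasets keep running.

Profile intervals were chosen over bootstrap or delta-method intervals
because they respect the strong asymmetry of BMD likelihoods, are
deterministic, and are directly testable against the defining chi-square
equation.

## Trend tests

The overall dose effect is screened with a Poisson regression
likelihood-ratio chi-square: dose as a categorical factor with the log
denominator as offset, against the intercept-only model (df = number of
dose levels - 1).  Each dose group is then compared with the vehicle
control by the df = 1 likelihood-ratio statistic obtained from constraining
that group's rate to the control rate, and the p-value is mapped to the
tier letters `a`/`b`/`c`/`d` (p < 0.0001/0.001/0.01/0.05) or `ns`.  No
multiplicity adjustment is applied across the per-dose contrasts -- the raw
tiered p-values are what this kind of study reports -- and the lowest dose
with a significant contrast is returned as the LOGEL.  Count endpoints are
tested on their raw counts and denominators; continuous DNA adduct
responses (reported per 1e8 nucleotides) are rounded to integer adduct
counts with a one-unit denominator so the same machinery applies.  No
overdispersion term is included; with seven animals per group the
categorical model already absorbs between-group heterogeneity, though
genuinely overdispersed counts would make the contrast p-values liberal (a
known limitation).

## Ranking, cross-endpoint comparison, proportionality

Tissues are ranked by the geometric midpoint of their BMD confidence
interval, and two tissues are called distinguishable exactly when their
intervals do not overlap.  Groups are formed by the transitive closure of
adjacent-interval overlap in midpoint order, which reproduces how such
studies verbally group tissues ("A > B/C > D/E/F").  Estimates whose BMDU
hit the search cap are ranked last and flagged.

Cross-endpoint comparison lines up, for one tissue or compartment, the
midpoints, CI ranges and the fitted maximum-response parameter `c`
(absent for models without an asymptote) -- the display that makes the
point that endpoints with small inducible ranges (micronuclei) cannot be
compared naively against endpoints spanning orders of magnitude (adducts).

The proportionality analysis formalizes the unity-slope double-log plot:
the offset of a slope-1 line through tissue-matched
`(log10 BMD_x, log10 BMD_y)` pairs is the mean paired difference, and
`10^offset` is the proportionality constant.  Adequacy of the unity slope
is tested by comparing the slope-1 residual sum of squares against the
free-slope least-squares fit with an F-test at the 0.05 level.  The visual
criterion this replaces has no printed numeric form; the F-test is one
defensible formalization and is labelled as such.  Pairs are unweighted by
default (the customary plot is unweighted); inverse-squared-CI-width
weights are available behind a flag.  The Ki-67 analysis correlates a
per-tissue proliferation index with the ratio of two endpoints' BMDs and
attaches an explicit small-sample caveat, since three tissues are the
practical minimum.

## The synthetic-data generator

No animal-level data accompany the study this package's design follows, so
the generator is a first-class module that emulates the stated design: 11
dose groups (0, 0.10, 0.20, 0.39, 0.78, 1.56, 3.13, 6.25, 12.50, 25.00,
50.00 mg/kg BW/day), 7 animals per treated group, 14 vehicle controls (84
animals).  Per animal, a log-normal biological factor multiplies the true
mean curve; continuous endpoints add log-normal assay noise, count
endpoints draw a denominator and then a Poisson count (mutant counts among
a large denominator) or binomial count (micronucleated cells among cells
scored).  Generation is deterministic given a seed and never perturbs the
caller's RNG state.

The preset registry fixes one generator configuration per tissue x endpoint
studied.  Its conventions, chosen once:

* **Backgrounds**: 0.5 adducts/1e8 nucleotides, 5 lacZ mutants/1e5 pfu,
  10 (RET) and 3 (RBC) Pig-a mutants/1e6 cells, 0.15%/0.10% micronucleated
  RET/NCE -- plausible spontaneous levels for this mouse model.
* **Denominators**: total pfu uniform on 2e5-5e5, 3e5 RET and 3e6 RBC
  interrogated, 2e4 cells scored for micronuclei -- plausible assay scales.
* **Noise**: between-animal CV 0.35 for the mutation endpoints, 0.15 for
  micronuclei; adduct assay log-SD 0.5 (which reproduces the wide adduct
  CIs -- precision ratios around or above 2 -- that such data show, against
  the consistently tighter lacZ intervals).
* **Maximum responses** `c` are anchored to the published fold-change
  increases over control (e.g. 506 for spleen adducts, 208 for
  small-intestine lacZ, 4.5 for micronucleated RET).
* **Shapes**: adducts and micronuclei are generated linear-saturating
  (`m4`); mutation endpoints superlinear (`m5`, `d = 2` for the sensitive
  lacZ tissues, `d = 3` for the insensitive ones and Pig-a).  The printed
  effect structure forces this: a tissue whose response is still
  background at the middle doses but 15-fold elevated at the top dose is
  geometrically incompatible with a `d = 1` saturating curve, and with
  `d = 1` the anchored maxima would never be observed inside the dose
  range.
* **BMD targets** reproduce the study's qualitative structure, not its
  unpublished numbers: lacZ BMDs 0.8 / 3.3, 3.5 / 10, 10.7, 11.5, 12.3
  mg/kg (three CI-separated groups: small intestine, then bone
  marrow/spleen, then the four insensitive tissues); adduct BMDs exactly
  lacZ/20 (so the generator embodies a perfectly proportional
  adduct-to-mutation conversion with constant 20) plus bladder at 0.55;
  Pig-a 5.5/7.0 and micronuclei 12/13, giving the hematopoietic
  progression adducts < mutation < micronuclei.

Zero counts are incompatible with log-scale modelling; the default rule
replaces a zero with half the smallest non-zero per-animal value in the
same dataset (an `exclude` alternative is available but refuses to empty a
dose group).  The rule only ever touches near-background animals and its
influence vanishes as the signal grows.

**What passing tests on these data do and do not show.**  The generator
draws from the same distributional families the models assume (log-normal
biological variation, Poisson/binomial counting).  Validation against it
therefore demonstrates internal correctness and calibration -- closed forms
match numeric inversion, profile CIs cover at their nominal rate, the
selection ladder holds its type-I error, the study's qualitative structure
is reproduced -- but not robustness to real-data pathologies such as
overdispersed counts, heteroscedastic assay noise, batch effects or
non-monotone dose-responses, none of which the generator emulates.

## Validation scale and numerical choices

The test suite validates at these problem sizes, chosen to give binomial
error bands tight enough to be meaningful: 1,000 random parameter draws per
model for the closed-form/bisection agreement (relative tolerance 1e-8);
300 seeded study replicates per preset for 90% CI coverage (band 86-94%);
500 no-effect replicates for the selection type-I error (band 3.2-7.2%
around the nominal 5%); 100 random datasets for the trend-test oracle
(tolerance 1e-6); 20 seeded runs for each qualitative-structure check.
Other numerics: optimizer relative tolerance 1e-10 on the concentrated
objective; bounds handled by log/logit transforms; profile roots to 1e-8 on
the log-dose scale; CSV round trips written with 17 significant digits.

## Known limitations

* Coverage of the profile CI is nominal only when the generating curve is
  identifiable within the family; after model selection the interval does
  not account for selection uncertainty, and borderline-curvature data can
  undercover.
* Count endpoints are modelled log-normally after conversion to rates,
  mirroring standard practice for these assays; for very low counts (a few
  mutants per animal) the approximation and the zero rule both bite, and
  coverage degrades gracefully rather than exactly holding.
* Decreasing dose-responses are detected but not modelled (no BMD for a
  declining endpoint); quantal (tumour yes/no) data are out of scope.
* The unity-slope F-test treats BMDs as error-free points; CI widths are
  displayed, not propagated.
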