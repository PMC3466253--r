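---
title: "Methods: models, nulls and numerical choices in phylorisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, nulls and numerical choices in phylorisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the statistical methods it
implements: what each procedure assumes, which knobs matter, what the
synthetic-data generators do and do not emulate, and where the design was
genuinely open and a choice had to be made.

## The analysis problem

A red-listed flora is a species checklist with IUCN categories. Two binary
questions structure everything here: is a species *threatened*
(EX, CR, EN or VU) or *not threatened* (LR/CD, NT or LC)? Data Deficient
species are excluded from analysis but always reported, never silently
dropped. The package asks whether this binary trait is selectively
distributed — over families (taxonomic selectivity), over the phylogeny
(phylogenetic signal), within individual categories (community structure)
— what time-varying model of trait evolution best describes it, and how
threatened richness maps onto block-level environment.

## Tree assembly from taxonomy

Most species in poorly sequenced floras have no phylogenetic placement, so
trees are assembled by grafting: a species is attached as a new tip below
the backbone node labelled with its genus, else its family, extending a
polytomy. Species with neither anchor go into an `unplaced` report. The
backbone is ordinary Newick with labelled interior nodes (a deliberate
simplification over parenthetical megatree formats: together with the
species table's genus/family columns it carries the same information), and
backbone structure below attachment points is never rearranged.

Dating follows the even-interpolation idea: tips are anchors at age 0,
labelled nodes found in the age table are anchors at their stated ages
(kept bit-exactly), and each undated node is spaced evenly between its
nearest dated ancestor and its nearest dated descendant, fewest edges
first, ties to the older age. Two numerical details matter:

* Nodes are processed root-to-tip, so a run of undated nodes is spaced
  evenly because each one anchors the next. This reproduces pencil-and-
  paper interpolation on chains (a node midway between a 10 My root and a
  tip gets 5 My; two nodes under a 12 My root get 8 and 4 My).
* A *monotonicity guard*: when an older calibration sits deeper in the
  subtree than the step-nearest anchor (possible with sparse, uneven
  calibrations), the interpolation re-anchors on that oldest dated
  descendant. Without the guard, a step-nearest tip at age 0 could pull a
  node below a deeper 60 My calibration; with it, parent ages strictly
  exceed child ages whenever the calibration set is internally consistent,
  and the output is exactly ultrametric. Inconsistent calibrations (a
  dated node older than its dated ancestor) are an error, not a warning.

Thinned trees address the opposite worry — that unresolved polytomies
inflate apparent signal. At every polytomy two child subtrees are kept
uniformly at random and the rest deleted outright; unary nodes are
suppressed with branch lengths merged. The result is a strictly
bifurcating topological restriction of the input. Deleting whole child
subtrees (not only tip children) makes the procedure terminate on any
topology in a single sweep per nesting level. Because each replicate
discards data, thinned-tree results are reported as a *range* over
replicates (default 100), never a single value.

## The D statistic

The conservatism score is the sum of sister-clade differences: nodal
values are unweighted means of child values, computed tips to root, and
each internal node contributes the summed absolute differences between its
children's values and its own (at a bifurcation this is just the
difference between the two child values; at a k-tomy every child deviation
counts). Branch lengths deliberately do not enter the score — they enter
only through the Brownian null — because D is self-normalizing: the same
estimator is applied to the observed states and to both nulls, so any
consistent estimator calibrates correctly.

Both nulls condition on the observed prevalence. The shuffle null permutes
the observed states across tips. The Brownian-threshold null simulates a
rate-1 Brownian character on the given branch lengths and assigns state 1
to exactly the top-prevalence-ranked tips — thresholding by rank rather
than by a fixed cut keeps the two nulls comparable. D is the observed
score positioned linearly between the two null means. Two one-sided
Monte-Carlo p-values accompany it, both with the add-one correction so no
p-value is ever 0: the probability the trait is no more clumped than
random, and the probability a Brownian trait is at least as dispersed as
observed. Both tails are reported because directional conventions differ
between studies.

Degenerate inputs (all tips in one state) are an explicit error: signal is
undefined, and an NaN would propagate silently.

`d_calibration()` packages the two anchor checks: across replicate
simulated datasets, mean D for shuffled traits should sit near 1 and mean
D for Brownian-threshold traits near 0. The test suite runs these at 100
datasets x 200 tips x 1000 permutations.

## Taxonomic selectivity

The family test permutes the binary labels across all assessed species,
holding family sizes and the total threatened count fixed (equivalent to
randomizing species-to-family membership, and cheaper). Each family gets
one-sided add-one p-values in both directions; families with no threatened
species are tallied separately because "no at-risk species" and
"significantly depleted" are different statements for small families. No
multiple-testing correction is applied across families — the per-family
p-values are descriptive, as is conventional for this analysis.

One property worth stating honestly: with a discrete count statistic the
permutation p-value is *conservative*. The null count for a family of m
species carries point masses of 0.01–0.03 in its tails at realistic m, so
the attained per-tail rate at a nominal 0.05 threshold is typically
0.03–0.045, not 0.05. This is a property of exact discrete tests, not an
implementation artifact; the add-one correction adds a further (1/(n_rand+1))
of conservatism. Calibration checks against an idealized 0.05 will
therefore read low.

## Community structure: NRI and NTI

For the species set of each category, mean pairwise patristic distance
(MPD) and mean nearest-taxon distance (MNTD) are computed on the dated
tree in My, then standardized against null sets of the same size drawn
uniformly without replacement from all tips (the phylogeny pool):
NRI = −(MPD_obs − mean_null)/sd_null, NTI likewise from MNTD. The sign is
flipped so clustered sets score positive. The p-value is one-tailed toward
clustering — the hypothesis these indices usually serve — with the
overdispersion tail recoverable as `1 - p + 1/(n_null + 1)`. Sets with
fewer than two species return NA metrics (a singleton has no pairwise
distances), mirroring the dashes such tables conventionally print.

## Evolutionary models of threat

Threat status is modelled as a symmetric two-state Markov chain (one rate
q, per My) on trees whose branch lengths encode time-varying rates:

* `delta`: node depths d are mapped to T·(d/T)^delta (T = tree depth).
  delta = 1 is the identity; delta > 1 concentrates evolution toward the
  present, delta < 1 toward the root.
* `linearChange`: instantaneous rate 1 + (endRate − 1)·t/T; each branch
  gets the closed-form integral.
* `twoRate`: rate 1 before a breakpoint B, endRate after; piecewise
  integral. endRate = 1 is the identity for any B.
* `null`: the untransformed tree.

All transforms rescale to preserve total depth; otherwise q and the
transform trade off unidentifiably and rates would not be comparable
across models. The likelihood is Felsenstein pruning with per-node
rescaling (stable on large trees), equal root frequencies (the simplest
convention for a symmetric model; an equilibrium or data-weighted root
prior is a defensible alternative but not the default), and impossible
configurations return a large negative log-likelihood rather than NaN.

Fitting maximizes over log-parameterized boxes (q and endRate/delta over
about six decades; the breakpoint on (0.02 T, 0.98 T) through a logistic
map) with L-BFGS-B from five starts per model. Free-parameter counts are
k = 1 (null), 2 (delta), 2 (linearChange), 3 (twoRate), and
AIC = −2 lnl + 2k is recomputed from the fitted likelihood — never
reconstructed from any published bookkeeping. Nesting is verified in the
tests: the null fit can never beat a transform fit by more than numerical
tolerance, since each transform contains the identity.

A caution from the package's own simulations: the transform parameters are
only identifiable in an informative rate regime. With many expected
changes per root-to-tip path (qT of a few), a binary trait saturates
toward tree-independent noise, the likelihood surface in delta flattens,
and boundary estimates appear. The recovery tests therefore simulate at
qT well below 1.

## Richness regressions

Threatened richness per block is regressed, after natural-log transforms
(base configurable; log-log slopes are base-invariant), on six predictors
one at a time — minimum, maximum and mean elevation, elevation range,
temperature, rainfall — and again with log block area as a covariate:
twelve OLS models ranked by AICc with
k = slopes + intercept + error variance. Only AICc *differences* are
interpreted, so the additive constant convention is immaterial. Blocks
with zero threatened species are an error by default (`log(0)`); an
explicit `add1` option exists because silently shifting counts is a choice
the analyst should own. Mean elevation is validated to equal
(min + max)/2 and range to equal max − min on input.

## What the generators emulate — and what they do not

The generators target the statistical structure the analyses assume, at
the scale of a national red-list checklist: 581 species, prevalence
298/581, 78 families, and threatened/lower-risk category subdivisions in
the proportions of a national tally (209 VU : 70 EN : 18 CR : 1 EX and
238 LC : 31 NT : 2 LR/CD) are the defaults. Trees are pure birth
(the simplest ultrametric generator; birth 0.045 per My gives root ages
near 140 My at that richness, an angiosperm-scale timescale). Threat is
assigned by one of three mechanisms spanning the D scale: uniformly random
tip sets (D ~ 1), rank-thresholded Brownian values (D ~ 0), and a single
conserved clade closest in size to the target prevalence (D < 0). The
prevalence is hit exactly after rounding — labels are a random subset of
fixed size, not independent coin flips — so nulls and generators condition
on the same quantity. Taxonomies are monophyletic by construction; the
label-based enrichment generator multiplies threat odds within chosen
families for selectivity power checks. Block tables embed a known log-log
elevation-range effect (defaults: intercept −8, slope 1.6, noise sd 0.4 on
the log scale) with temperature following a 6.5 °C/km lapse rate.

What passing tests on these data do *not* show: real red lists have
non-random assessment effort, paraphyletic taxonomies, correlated threat
drivers, birth–death (not pure-birth) trees, and spatially autocorrelated
environments. Calibration on the generators validates the machinery, not
any empirical claim about a particular flora.

## Problem sizes in the tests

The routine suite runs at reduced scale (tens of replicates, hundreds of
permutations); the headline calibrations run at 100 datasets x 200 tips x
1000 permutations for D, 500 replicate sets x 1000 null draws for NRI/NTI,
600 families for selectivity calibration, and 100 seeds for regression
recovery — sizes at which the Monte-Carlo error of each check is small
relative to its tolerance.

## Known limitations

* Grafting resolves placement only to genus/family anchors; within-anchor
  relationships are polytomies by construction.
* The even-interpolation dating has no notion of rate smoothing; ages
  between anchors are linear in edge counts.
* The Mk2 model is symmetric; asymmetric gain/loss of threat status is not
  fitted.
* NRI/NTI use presence only; abundance weighting and alternative null
  models (label shuffles within subsets, independent swaps) are out of
  scope.
* Regressions are ordinary least squares; spatial autocorrelation between
  blocks is not modelled.
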