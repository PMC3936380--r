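---
title: "Methods: single-locus phylogeography with phylorefugia"
author: "phylorefugia authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-locus phylogeography with phylorefugia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylorefugia)
```

## Scope and study design

`phylorefugia` implements the analysis chain used to dissect the history of
a species sampled as haploid, non-recombining sequence data (typically
concatenated chloroplast loci) across structured populations — for example
a cloud-forest tree with populations on either side of a montane barrier
such as the Trans-Mexican Volcanic Belt, and a disjunction from temperate
relatives further north.  The chain is:

1. collapse aligned sequences into haplotypes and build a
   statistical-parsimony network;
2. summarize diversity and differentiation (haplotype and nucleotide
   diversity, pairwise Phi-ST, Pons–Petit ordered vs. unordered
   differentiation with the N~ST~ > G~ST~ permutation test);
3. partition molecular variance hierarchically (AMOVA) and search for the
   spatial grouping maximizing the among-group component (SAMOVA);
4. probe historical demography (Tajima's D, Fu's F~s~, mismatch
   distributions under sudden expansion);
5. convert mutation-scaled demographic estimates into years, effective
   sizes and migrants;
6. test refugial scenarios by structured-coalescent simulation and the
   Slatkin–Maddison *s* statistic; and
7. test niche divergence versus conservatism against a background null.

Every stage can be exercised on data from the built-in generator, whose
defaults encode the survey design the methods assume: 19 populations of
2–14 haploid samples (160 in total) in two groups split by a barrier, a
1417-bp locus, substitution rate 1.59 × 10⁻⁹ per site per year, generation
time 34 years, deme size 10,000 gene copies, and a split 1.8 Myr ago.  The
deme size was picked so that a survey of this shape yields on the order of
ten segregating sites, the regime these statistics are used in; the split
time sits in the middle of the Pliocene–Pleistocene range relevant to
montane vicariance.  These defaults are study conditions, not tuning knobs.

## The synthetic-data generator

`simulate_sequences()` draws a genealogy from the structured coalescent
(each group of populations is one panmictic deme; see below) and evolves
sequences down it under a **finite-sites Jukes–Cantor** process:
substitutions arrive as Poisson events with mean `mu · L · branch length`,
each hitting a uniformly chosen site and moving it to one of the other
three bases.  Finite sites (rather than infinite sites) are deliberate:
real chloroplast data show indel runs and occasional homoplasy, and the
haplotype machinery must cope with multiple hits.  Indels are a separate
deletion-only process at 5% of the substitution rate, producing 1–3 bp gap
runs that descendants inherit — enough to exercise both gap-handling
modes.  Populations sit on a linear transect with an extra gap between
groups so that spatial contiguity in SAMOVA is meaningful.

What the generator does **not** emulate: recombination (the locus is one
non-recombining block, appropriate for cpDNA), selection, real geographic
rasters, and within-group population differentiation (populations inside a
group share one deme, so tests that pass here say nothing about isolation
by distance within groups).  Conclusions from passing tests therefore
transfer to real data only in so far as the single-locus, island-like
structure holds.

`simulate_niche_data()` draws occurrence and background environmental
vectors from lineage- and background-specific multivariate normals.  It
reproduces the *statistical* structure of a niche-background test (two
lineages with shifted means inside broader overlapping backgrounds), not
the spatial autocorrelation of real climate layers.

## Haplotypes and the parsimony network

Two gap modes are supported, matching the two conventions used for
combined versus regional datasets: `missing` (sites with a gap in either
sequence are ignored in the comparison; pairwise deletion is used for all
distances) and `fifth_state` (`-` is a character state).  Under `missing`
the identity relation is not transitive, so sequences are assigned
greedily to the first matching haplotype in input order — the same
convention standard collapsers use; the result depends on input order only
in the rare ambiguous cases.

The connection limit of the statistical-parsimony network is the largest
number of steps *j* for which the probability that all *j* observed
differences are single mutations exceeds 95%.  We compute that probability
under a Poisson multiple-hit model on a Jukes–Cantor locus: the per-site
hit count is Poisson(λ) with λ solving the JC relation
(3/4)(1 − e^(−4λ/3)) = *j*/*L*, and the probability that a differing site
is parsimonious is P(exactly one hit)/P(site differs); the *j*-th power of
that ratio is the parsimony probability.  At *L* = 1417 and 95% this gives
a limit of 14 steps.  Beyond the JC saturation point the divergence
estimate is capped so the probability stays positive (and vanishingly
small); as the confidence level tends to zero, every connection up to the
locus length becomes allowed.

Network construction is a minimum-spanning pass over haplotype pairs
ordered by distance, inserting anonymous intermediates for multi-step
connections.  Full loop resolution by topology/geography requires curator
judgment; we implement only the frequency criterion — among equal-length
alternatives the edge whose endpoints carry more samples wins — and report
every discarded alternative so that loops can be audited.

## Diversity and differentiation

Per-population gene diversity uses the unbiased estimator
h = n/(n−1)(1 − Σp²); nucleotide diversity is the mean pairwise proportion
of differing sites.  The Pons–Petit framework contrasts **unordered**
statistics (h~S~, h~T~; haplotype identity only) with **ordered** ones
(v~S~, v~T~; weighted by mutational distances between haplotypes):
G~ST~ = 1 − h~S~/h~T~ and N~ST~ = 1 − v~S~/v~T~.  Within-population terms
are debiased by n/(n−1), populations are weighted equally, and the total
diversity carries the h~S~/(ñK) small-sample correction (ñ the harmonic
mean sample size) — the Nei–Chesser-type estimators the Pons–Petit method
builds on.  The published variance formulas for these estimators are long
and easy to mistranscribe; we instead report delete-one-population
jackknife standard errors, which estimate the same between-population
sampling variability and are reproducible from first principles.

N~ST~ exceeding G~ST~ indicates that closely related haplotypes co-occur
within populations — phylogeographic structure.  The permutation test
shuffles haplotype identities on the distance matrix (rows and columns
jointly), which preserves the frequency structure (G~ST~ is unchanged)
while destroying the association between relatedness and location;
the one-sided p-value is the add-one-corrected fraction of permutations
with N~ST~ − G~ST~ at least the observed difference.  Individuals are not
reshuffled: the question is about the arrangement of distances, not of
samples.  Haplotype distances default to raw mismatch counts; network
step counts can be supplied instead when a network is available.

Negative differentiation estimates are reported as computed and flagged,
never truncated.

## AMOVA and SAMOVA

AMOVA treats the matrix of pairwise differences as squared distances (the
molecular-variance convention, so "distance" inputs are mismatch counts or
TN93-corrected counts) and partitions the total sum of squares into
among-group, among-population-within-group and within-population
components, equating observed and expected mean squares with the standard
unequal-sample-size coefficients.  With every population its own group the
design collapses cleanly to the two-level analysis.  Permutation schemes
follow the hierarchy: individuals across the whole system for F~ST~,
individuals within groups for F~SC~, whole populations among groups for
F~CT~, with p = (count ≥ observed + 1)/(n + 1).

Whether published tables of this kind used raw or TN93-corrected
differences is usually ambiguous; both are provided
(`pairwise_distance_matrix(model = "raw" | "tamura_nei")`) and the default
is raw, since the testing logic is unaffected by the correction at low
divergence.

SAMOVA searches contiguous K-partitions of the population neighborhood
graph (Delaunay triangulation, computed by the empty-circumcircle
criterion; collinear layouts degrade to chain adjacency).  Each annealing
run starts from a random contiguous partition and proposes single-
population moves to adjacent groups that keep every group non-empty and
connected; improvements are always accepted, worsening moves with
probability exp(Δ/T).  The initial temperature is set from the mean |Δ| of
a few probe moves so that an average worsening move is accepted with
probability about one half, with geometric 0.9 cooling over the run (1000
proposals by default, 100 runs).  Ties across runs resolve to the first
occurrence in seed order.  On small systems the annealer reproduces the
exhaustive contiguous-bipartition optimum exactly (this is tested), and
the selection heuristic — pick the K with the largest F~CT~ before group
structure dissolves — behaves as expected on simulated splits.

## Historical demography

Tajima's D uses the textbook constants; its p-value comes from neutral
constant-size coalescent simulations conditioned on the observed number of
segregating sites, reported as P(D_sim ≤ D_obs) so that small values flag
the significant negative D expected under growth.  Fu's F~s~ is computed
exactly: S′ = P(K ≥ k_obs | θ = θ~π~) under the Ewens sampling
distribution via unsigned Stirling numbers of the first kind evaluated in
log space, then F~s~ = ln S′/(1 − S′); the optional p-value simulates K by
the sequential urn construction at the same θ.

The mismatch analysis fits the sudden-expansion expectation
F_i(τ, θ₀, θ₁) — equilibrium geometric mixtures joined by a Poisson(τ)
convolution — by Nelder–Mead least squares on SSD from several
moment-based starts, with τ and θ₀ positive and θ₁ ≥ θ₀ enforced through
the parameterization.  Goodness of fit is by parametric bootstrap:
datasets are simulated under the fitted expansion (a piecewise-constant
coalescent in mutational time), refit, and p_SSD is the fraction of
simulated SSDs at least the observed.  The raggedness index is the sum of
squared successive frequency differences.  The bootstrap default here is
1000 replicates (the conventional reporting default is 10,000); the test
suite uses smaller bootstrap sizes, which changes only the resolution of
the p-values, not their validity.

## Unit conversions

All conversions are pure functions: generation time T = a + s/(1 − s);
per-lineage substitution rate (D~xy~/2)/(2t_div); mutation-scaled times
t/(μL); mutation-scaled sizes q/(c·μL·g) with the inheritance scalar c
exposed as a parameter (default 2, the convention for a haploid,
uniparentally inherited organellar locus — not hard-coded into any
result); population migration rate qm/c.  Rounding to printed precision
happens only at the reporting layer.  Note that a per-Myr rate of
1.59 × 10⁻⁴ corresponds to 1.59 × 10⁻¹⁰ per year; both scales are returned
so the caller can choose explicitly.

## Coalescent simulation and refugial hypothesis tests

The simulator is an event-driven structured coalescent: within a deme of
N gene copies each lineage pair coalesces at rate 1/N per generation
(exact exponential waiting times, no discrete generations); join events
pool demes going back in time; optional migration moves single lineages
between active demes.  Two scenario presets encode the competing
histories: **two refugia** (two demes of size Ne isolated since T,
ancestral size Ne) and **fragmentation** (one deme of size Ne splitting
into two of Ne/2 at T, conserving total size).  The structural difference
between such hypothesis families is rarely pinned down in the literature;
these presets are one defensible reading, fully overridable through
`population_model()`.

The Slatkin–Maddison *s* statistic is the Fitch parsimony count of
deme-label changes on the gene tree (topology only).  `refugia_test()`
compares an observed *s* — from a labeled tree or supplied directly, as
when only the published statistic is available — with the central 95% of
*s* over 1000 simulated genealogies per scenario (2.5th/97.5th empirical
percentiles, linear interpolation); falling outside rejects the scenario.
Whether the published comparisons were one- or two-tailed is typically
unstated; the two-tailed central interval is the default and an
upper-tail variant is available (`tail = "upper"`).

A caveat established by the calibration tests: because *s* is integer-
valued, the falls-outside rule is conservative — when the simulated *s*
distribution is concentrated on a few values the self-rejection rate falls
far below the nominal 5%.  The calibration check therefore uses a
scenario chosen (before running the check) for a well-dispersed *s*
distribution: two refugia of 10,000 gene copies isolated for 2000
generations with 20 samples per deme, where the rate is close to nominal.
Users comparing scenarios with near-complete lineage sorting should expect
the test to be conservative, not anti-conservative.

## Niche divergence versus conservatism

`pca_env()` extracts shared niche axes from the pooled
occurrence-plus-background matrix (correlation matrix by default — the 19
bioclimatic variables are on different scales — covariance by option);
axes are fitted on the pooled set so both lineages and both backgrounds
are scored in one space.  On each axis the observed statistic is the
absolute difference of lineage means; the null is the middle 95% of the
background divergence recomputed over 1000 jackknife replicates, each
resampling 75% of each background with replacement ("75% of replacement"
is ambiguous in the literature; both the fraction and the
with/without-replacement choice are parameters).  Divergence is called
above the interval, conservatism below, neither inside.

The null behaviour of this background test depends on the ratio of
occurrence to background sample sizes: the observed difference carries the
sampling noise of the occurrence means, while the interval width reflects
only background resampling.  With few occurrences and many background
points the test is anti-conservative under identical distributions.  The
package's null-case check therefore uses equal occurrence and background
sizes; with survey-like ratios (say 100 occurrences against 1000
background points) "neither" rates under the null drop well below
nominal, a property users should keep in mind when interpreting calls.

Background points are drawn geographically: a minimum convex polygon
around the occurrences and uniform rejection sampling inside it.  Pairing
sampled points with environmental values is the caller's responsibility
(no raster engine is in scope).

## Numerical choices and problem sizes

Tolerances and tie-breaks worth knowing: distances of zero never create
network edges (identical haplotypes are collapsed first); equal-distance
network edges are ordered by total endpoint frequency; annealing ties
resolve to the first-seen optimum; monomorphic systems and zero-variance
AMOVAs return flagged `NA` indices rather than 0/0; negative variance
components and differentiation estimates are reported as computed.  All
stochastic functions take an explicit seed and are bit-reproducible under
it.

The test suite runs the stochastic calibrations at deliberately modest
sizes — 200 calibration trials of 1000 simulated genealogies, 50-replicate
power checks with 500 permutations, bootstrap sizes of 60–100 — chosen so
the full suite completes on a single CPU in minutes while leaving the
binomial error of each check well inside its asserted band.  The same
sizes are used by `scripts/acceptance.R`, which recomputes the headline
quantities from scratch.

## Known limitations

Single locus throughout (no multi-locus AMOVA or IM estimation — only the
output scaling of an IM sampler is implemented); no recombination,
selection or spatial rasters; loop resolution reduced to the frequency
criterion; the mismatch machinery covers the sudden-expansion model only
(no spatial expansion, no multimodality tests); Bayesian tree/skyline
estimation is out of scope, and observed genealogies enter as Newick trees
with a tip-to-deme map.
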