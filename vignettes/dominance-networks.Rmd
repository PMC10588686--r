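---
title: "Dominance hierarchies and quantitative visitation networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dominance hierarchies and quantitative visitation networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dominet)
```

`dominet` links two kinds of field data on a hummingbird community: a
tournament of agonistic contests (who displaces whom at a floral patch) and
a quantitative bipartite visitation network (how many legitimate flower
visits each hummingbird species pays each plant species). This vignette is
the package's own account of the methods: the models, their assumptions,
the tunable parameters, and the numerical and design choices made where the
methods literature leaves them open.

## Dominance hierarchy

**David's score.** For species $i$ and $j$, let $P_{ij}$ be the proportion
of observed contests between them won by $i$. Unobserved dyads contribute
nothing — the index is built for incomplete tournaments, where typically
half of all dyads are never seen contesting. With
$w_i = \sum_j P_{ij}$, $w^{(2)}_i = \sum_j P_{ij} w_j$,
$l_i = \sum_j P_{ji}$ and $l^{(2)}_i = \sum_j P_{ji} l_j$,

$$Ds_i = w_i + w^{(2)}_i - l_i - l^{(2)}_i,$$

which sums to zero over the community (an algebraic identity the tests
assert at $10^{-9}$). We use raw win proportions; a sample-size-corrected
variant is deliberately not the default because the uncorrected form is the
one commonly reported, and the correction is a one-line change where
wanted.

**Dominance probabilities and certainty.** Direct wins are augmented with
indirect win-pathways through common third parties: a directed path
$i \to k \to j$ in the binarized win-majority graph adds
$\lambda^{(\ell-1)}$ units of flow for a path of length $\ell$ (default
maximum length 2, decay $\lambda = 0.5$). Pathway-augmented flow $F$ is
smoothed with half-unit pseudo-counts,
$P_{ij} = (F_{ij} + 0.5)/(F_{ij} + F_{ji} + 1)$, so a dyad with no
information sits exactly at $0.5$. This pathway construction is our
documented reconstruction of the percolation-and-conductance family of
methods, whose published descriptions do not pin down the path weighting;
all three knobs (path length, decay, pseudo-count) are arguments, and we
flag the construction as analogous to, not identical with, any specific
implementation. Dominance certainty is
$DC_i = \mathrm{mean}_j \max(P_{ij}, P_{ji})$, ranging from 0.5 (coin-flip
position) to 1 (fully certain). Species at $DC \le 0.5$ — typically rare
species with almost no contests — are dropped by
`filter_uncertain_species()` and the hierarchy recomputed, mirroring
standard practice.

**Rank order.** The ordering maximizing
$\sum_{i \prec j} P_{ij}$ is found by simulated annealing (geometric
cooling, 10 restarts, pairwise-swap polishing, ties broken by input
order, deterministic given its seed). For $n \le 6$ the tests verify the
annealer against exhaustive permutation search. The rank index rescales
ordinal ranks to $[0, 1]$, 0 for the top species.

## Network structure

**Specialization $d'$.** For each consumer row with total $r$ and partner
availability $q_j$ (column totals over the grand total), the
Kullback–Leibler divergence $d = \sum_j p'_j \ln(p'_j/q_j)$ of its use
distribution is normalized by the extremes achievable when reallocating
the *same integer total*: $d' = (d - d_{\min})/(d_{\max} - d_{\min})$.
The extremal allocations are computed by explicit integer algorithms —
$d_{\min}$ by largest-remainder proportional rounding of $r q_j$,
$d_{\max}$ by loading units greedily where the divergence gain is largest
(rarest partner on ties). Published implementations delegate these
extremes to unstated heuristics; ours are specified exactly and verified
against exhaustive enumeration of all integer allocations at small totals.
Rows with zero totals get `NA` (flagged, excluded from regressions)
rather than an error.

**Barber modularity and DIRTLPAwb+.** Weighted bipartite modularity
$Q = F^{-1} \sum_{ij} (a_{ij} - r_i c_j / F)\,\delta(g_i, h_j)$ is
maximized by a restart-wrapped label-propagation search: each run starts
from a random column partition at a random granularity (one run always
starts fully split), alternates best-label updates between guilds — each
sweep is exactly monotone in $Q$ because row scores depend only on column
labels and vice versa — and then greedily merges module pairs while $Q$
improves, re-propagating after each merge. The best of `n_runs` runs
(default 50) is returned, and the returned $Q$ always equals Barber's
formula recomputed on the returned labels. A note on budgets: quantitative
descriptions of this algorithm sometimes quote an "MCMC move" budget; the
algorithm is not MCMC, and we expose a sweep budget instead.

**Patefield null and z-score.** Null networks with exactly the observed
margins are drawn by Patefield's algorithm (`stats::r2dtable`); each of
`n_null` (default 100) replicates gets the *same* search budget as the
observed network, to avoid inflating $z$ by optimizing the observed
network harder than its nulls. $z = (Q_{obs} - \bar Q_{null})/s_{null}$;
a degenerate null ensemble (a fully margin-determined table) yields an
infinite $z$ with a warning rather than a division by zero. On
planted-partition fixtures the search recovers the true modules (NMI
$\ge 0.9$) and $z \gg 3$; on matrices that are themselves Patefield draws,
$|z| \le 3$ in the large majority of seeds. Note that a modularity
*maximizer* on pure noise still returns small positive $Q$ with more than
one module — that is precisely why the null ensemble, not the module
count, carries the inference.

**Core–periphery.** Each guild is split into core and periphery to
maximize a degree-corrected two-block log-likelihood
$\sum_b E_b \ln\!\big(E_b/(K_b D_b)\big)$ by greedy single-species flips
from several deterministic initializations (weighted-degree median split
and variants). The block pair of higher weighted connectance is labelled
the core, and $CPness = (E_{11} + E_{12} + E_{21})/F$ — the interaction
weight outside the periphery–periphery corner. The greedy search matches
exhaustive search over all $2^{r+c}$ assignments on 4×4 fixtures. A
consequence of the orientation rule worth noting: a network whose weight
is confined to one block reports $CPness = 1$, because that block *is*
the core by definition.

## Interaction-frequency model

The response is the visit count of every hummingbird × plant pair,
structural zeros included — a model of pairwise interaction frequency
needs the full factorial, and we flag this inclusion as an assumption
(the alternative, dropping never-observed pairs, conditions on the
outcome). Predictors: guild abundance proportions, calories per flower
(nectar volume in µL × sucrose molarity × 1.34; Brix is converted to
molarity as $\mathrm{Brix} \times 10/342.3$, isolated in
`brix_to_molarity()` so a density-corrected conversion is a one-line
change), calories per species (per flower × flower abundance),
morphological match (Euclidean distance between bill and corolla
length/curvature after z-scoring each trait within its own guild; larger
= worse match), corolla length, bill length, weight, and David's score.

The model is a negative-binomial GAM with log link: one univariate cubic
P-spline (second-order difference penalty, basis size 10, reduced to the
number of distinct values where a predictor has fewer) per predictor.
Smoothing parameters are selected by GCV with each model degree of
freedom costed at $\gamma = 1.4$ — the standard anti-overfitting
inflation. The NB dispersion $\theta$ is estimated by outer profile
likelihood: `optimize()` over $\log\theta$ of the NB log-likelihood at
the GCV fit, which recovers generating values well (e.g. $\hat\theta
\approx 2$ from data simulated at $\theta = 2$).

**A calibration caveat we measured rather than hid.** p-values for
GCV-selected smooths are known to be anti-conservative (smoothing
parameter selection is not accounted for; under REML they are much closer
to nominal). In our size simulations — 130 pairs, response a pure
abundance-product NB($\theta = 2$) with no trait effects — a pure-noise
species-level trait is "significant" at $\alpha = 0.05$ in roughly 17% of
seeds under GCV/$\gamma = 1.4$ (about 12% for a pair-level noise trait),
versus about 8% for the same data under REML. We keep GCV as the default
because it is the method this analysis tradition prescribes, and we
report the miscalibration here and in the test suite (where the
corresponding 10% bound is asserted and fails) instead of silently
switching criteria. Power is unaffected in practice: true abundance
smooths are detected in well over 90% of seeds. Readers doing fresh
analyses should prefer `method = "REML"`-style inference; readers
comparing against this tradition should know its p-values run small.

A second identity worth stating precisely: the familiar "fitted totals
equal observed totals" property of log-link count GLMs is exact only for
the canonical case. The NB log link is non-canonical — the intercept
score is $\sum (y_i - \mu_i)/(1 + \mu_i/\theta) = 0$ — so totals match
exactly only in the Poisson (large-$\theta$) limit, where our tests
assert it at 0.1%; at moderate $\theta$ a few-percent imbalance is
expected behaviour, not a bug.

## Closing statistics

PCAs are correlation-matrix eigendecompositions; axis signs are fixed by
making each axis's largest-magnitude loading positive, and per-variable
contributions are $100 \times$ squared eigenvector entries (summing to
100 per axis). Regressions are simple least squares with
$F = (n-2) R^2/(1 - R^2)$; the reported denominator degrees of freedom
are always $n - 2$ (published tables in this literature occasionally
print inconsistent df; $R^2$ is df-free and echoed for comparison).
Weighting by the square root of species' total interaction frequency is
available but off by default, because descriptions of where that
weighting enters are ambiguous.

## The synthetic community

The generators exist so that every downstream stage is testable without
the field data, and their defaults *are* the study conditions: 13
hummingbird and 10 plant species, 477 contests, 2,272 visits, and dyad
observability 0.45 (so roughly 55% of dyads go unobserved). Choices the
study does not fix were made once, on field-realism grounds:

* **Contest model.** Win probability is logistic in the latent-score
  difference (Bradley–Terry form), steepness 2.5 by default — a strong
  but noisy hierarchy. Latent scores are evenly spread; abundances follow
  a fixed lognormal profile (a few common species dominate), which is the
  regime in which abundance-driven ("neutral") network structure arises.
* **Visitation mixture.** Cell probabilities mix three normalized
  drivers — neutral abundance products (weight 0.6), morphological match
  $e^{-d_{ij}}$ (0.15), and a dominance driver (0.25) in which each
  species' preference for high-calorie plants is a softmax whose
  sharpness decays linearly with its rank, so the top species
  concentrates on the richest plants and the bottom species visits
  indiscriminately. Each component is normalized before mixing so the
  weights are interpretable mixture proportions. The trait tables give
  one plant an agave-like profile (copious nectar, short corolla, highest
  abundance) so a high-energy resource exists to monopolize.
* **Recovery regime.** The "strong hierarchy" used for parameter-recovery
  checks (Spearman between estimated David's scores and latent scores
  $\ge 0.9$) is 600 contests with all dyads observable — at least 30
  contests per species, the point at which David's score stabilizes.

What the generator does *not* emulate: phenology (no within-season
turnover), space (no patches or territories), individual birds (species
are exchangeable within their label), and observation error in visit
identification. Passing tests therefore demonstrate that the *methods*
behave correctly on data with the assumed statistical structure, not that
the assumed structure exhausts real field data.

## Problem sizes and determinism

All stochastic components (generators, Patefield draws, label
propagation, annealing) draw from streams derived from one integer seed
and are bit-reproducible; package functions never disturb the caller's
RNG state. The test suite exercises the community-scale problem (13×10,
2,272 visits) directly and uses 10–50-seed replicate experiments for the
distributional guarantees, with exhaustive-enumeration oracles at small
sizes (tournaments to $n = 8$, orderings to $n = 6$, integer allocations
to totals of 12, core/periphery splits on 4×4); the modularity z-score
experiments use 30 nulls × 5 runs per seed, and the end-to-end pipeline
defaults to the field-standard 50 runs × 100 nulls, which completes in a
few seconds on the 13×10 network.
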