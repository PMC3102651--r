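---
title: "Estimating divergence time and gene flow from coarsened joint site-frequency spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating divergence time and gene flow from coarsened joint site-frequency spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`imsfs` estimates speciation parameters of the neutral two-population
isolation-migration (IM) model.  An ancestral population (scaled mutation
rate $\theta_A = 4N_A\mu L$ per locus) splits $\tau$ time units ago — in
units of $2N_1$ generations — into two populations with rates $\theta_1$ and
$\theta_2$ that exchange migrants at scaled rates $M_{12} = 4N_2 m_{12}$ and
$M_{21} = 4N_1 m_{21}$, where $m_{12}$ is the fraction of population 2
replaced by migrants from population 1 each generation.  Loci recombine
internally at scaled rate $\rho = 4N_1 c L$ per locus and mutate under the
infinite-sites model; an outgroup is assumed to polarize alleles into
ancestral (0) and derived (1).

The data summary is the joint site-frequency spectrum (JSFS): the matrix $S$
whose entry $S_{i,j}$ counts polymorphic sites carried by $i$ of the $n_1$
sequences sampled from population 1 and $j$ of the $n_2$ from population 2.
The package estimates $\Theta = (\tau, M_{12}, M_{21})$, treating the
$\theta$'s and $\rho$ as known nuisance parameters — the setting in which
all of its validation experiments are run.

## Coarsenings of the JSFS

Rather than using the full $(n_1+1)\times(n_2+1)$ array, the estimators work
from *coarsenings*: ordered partitions of the eligible JSFS cells (all cells
except the unobservable corners $(0,0)$ and $(n_1,n_2)$) into labelled
classes; the data reduce to the class totals.  Six built-ins are provided:
the classical 4-class vector `W` (private in 1, private in 2, fixed
differences, shared), a 7-class refinement `D` that splits each private
class by whether the derived allele is absent or fixed in the other
population (so `W1 = D1 + D6`, `W2 = D2 + D7`, `W3 = D3 + D4`, `W4 = D5`),
two 12-class refinements `Dprime` and `Dsecond` that subdivide the shared
class around shared singletons and doubletons, and two 23-class refinements
`Dstar` and `Dcheck` that additionally bin the private classes by frequency
({1}, {2}, {3..n-1}) and split the shared class 3-by-3.  `Dcheck` uses
shared bins low = {1,2}, mid, high = {n-2, n-1}, adding classes of shared
polymorphism at nearly fixed frequencies; its class 6 collects sites that
are singletons or doubletons in *both* populations, the signature of recent
migrants.

The finer splits beyond the constraints above (class counts, the
`W`-from-`D` identities, the meaning of class 6, the nearly-fixed shared
bins) are package defaults: no authoritative cell-by-cell definition of the
12- and 23-class refinements exists, so the defaults were chosen once to
satisfy every such constraint and are clearly swappable — any alternative partition can be
supplied as a plain-text spec via `load_coarsening()`, which validates
disjointness and coverage by exhaustive cell enumeration and fails loudly
otherwise.

## The built-in coalescent simulator

No coalescent simulator with divergence, directional migration and
intra-locus recombination is available in the dependency stack, so the
package implements the standard Hudson-style ancestral recombination graph
(ARG) simulation in C++: lineages carry sorted lists of ancestral segments,
each tagged with the set of sample tips it subtends; coalescence merges
segment lists (dropping locally coalesced material), recombination splits a
lineage at a breakpoint drawn uniformly over its ancestral span (trapped
material included), and migration relabels a lineage's population.  Time is
measured in units of $2N_1$ generations throughout, so a branch of length
$t$ carries Poisson($\theta t/2$) mutations and no unit conversions exist
anywhere in the code; the Watterson limit $E[S] = \theta\sum_{i<n} 1/i$ at
$\tau = 0$ is an automated test.  Samples are capped at $n_1 + n_2 \le 64$
so that tip sets fit in one machine word.

Two observations make the estimators affordable.  First, conditional on the
ARG of a locus, the count in JSFS cell $(i,j)$ is Poisson with mean
$(\theta_1/2)\,L_{i,j}$, where $L_{i,j}$ is the span-weighted length of
branches subtending $i$ population-1 and $j$ population-2 tips; the
simulation fast path (`simulate_jsfs()`) therefore draws cell counts
directly from the branch-length spectrum without per-mutation bookkeeping.
Second, branch lengths are flushed lazily — a lineage contributes to
$L$ only when an event modifies it — which makes the frequent migration
events O(1).

## The genealogy-averaged maximum-likelihood route

For a locus summarized by class counts $F_1,\dots,F_K$, the likelihood of
$\Theta$ is approximated by Monte Carlo over $I$ simulated genealogies
$G_1,\dots,G_I$:
$$
p(F \mid \Theta) \approx \frac1I \sum_{m=1}^I \prod_{k=1}^K
\text{Pois}\!\left(F_k ;\; \tfrac{\theta_1}{2} L_k(G_m)\right),
$$
with $L_k(G)$ the branch length summed over the cells of class $k$.  Loci
are independent, so their log-likelihoods add.  `grid_loglik()` evaluates
this on a grid over $(\tau, M_{12}, M_{21})$; one genealogy pool per grid
node is shared across loci, which is exact here because loci are
exchangeable (identical sample sizes and nuisance parameters) and reduces
the simulation cost by the number of loci.  All products are accumulated in
log space via the log-gamma form of the Poisson pmf; configurations that
are strictly impossible (a positive count in a class with zero branch
length in every pooled genealogy) give $-\infty$, never `NaN`.

`maximize_surface()` maximizes by local regression with `stats::loess` — a
local quadratic with tricube weights and nearest-neighbour span 0.3 —
evaluated on
a 10-fold refinement of the grid and polished by bounded quasi-Newton
ascent on the smoothed surface.  Ties break towards the smallest
$(\tau, M_{12}, M_{21})$ lexicographically on the log scale.  The default
$I$ is 10,000; the tests use 25-1,000, which is enough for the oracle and
invariance checks but not for production inference.

## The composite-likelihood route

The fast estimator treats the pooled class counts of all loci as
independent Poisson variables — a good approximation when intra-locus
recombination is high, since recombination decorrelates sites.  It works in
three data-independent steps:

1. **Training grid** (`build_training_grid()`): 40 log-spaced values per
   parameter axis on $[0.01, 10]$ by default, 10 simulated datasets per
   combination, each reduced to its summary vector.  Log spacing
   concentrates resolution at recent divergence and weak gene flow.
2. **Block regressions** (`fit_block_models()`): the grid is cut into
   $8\times8\times8$ blocks (5 grid values per axis each at full scale).
   Per block $b$ and class $k$ a log-linear Poisson regression
   $\log E[F_k] = \beta_{1,k} + \beta_{2,k}\log\tau + \beta_{3,k}\log M_{12}
   + \beta_{4,k}\log M_{21}$ is fitted by IRLS (`stats::glm.fit`) on the
   block's records, with covariates centred at the block's log-scale
   center.  Classes with all-zero counts in a block are flagged degenerate
   and predicted at $\varepsilon = 10^{-10}$; a non-converging fit falls
   back to the intercept-only model and is flagged.  Parameter values of
   exactly 0 are replaced by $10^{-3}$ times the axis lower bound before
   the log transform.
3. **Estimation** (`im_estimate()`): with observed counts $F$ and model
   predictions $d(\phi)$, the composite log-likelihood is $\sum_k F_k\log
   d_k - d_k - \log\Gamma(F_k+1)$.  Strategy `J1` returns the best block
   center; `J2` the likelihood-weighted mean of the centers (weights
   $\propto$ the center likelihoods), averaged on the log-parameter scale —
   the scale on which the grid and regressions live — and reported on the
   natural scale; `J3` runs a bounded Nelder-Mead ascent inside every block
   (logistic reparametrization of the block box, at most 500 evaluations,
   log-likelihood tolerance $10^{-6}$); `J4` lets those ascents cross block
   boundaries, blending the predictions of adjacent blocks within half a
   grid step of a boundary with weights linear in log-parameter distance.

Because training never sees the data, a fitted model is reusable for any
dataset with the same sample sizes, locus count and nuisance parameters;
`im_estimate()` enforces this with a configuration fingerprint and refuses
mismatches.  Serialization (`write_blockmodel()`) round-trips the model
bit-identically.

Confidence regions come from the chi-square approximation to the
log-likelihood-ratio: the region is every $\phi$ on an evaluation lattice
within $\chi^2_{df}(0.95)/2$ of the lattice maximum ($\approx 2.99$ for
$df = 2$).  The two-parameter version profiles symmetric migration
($M_{12} = M_{21}$), matching the validation design; $df = 3$ is available
as an option.  The default lattice is the block centers — the same points
whose likelihood values drive J1/J2, and the points where the centred
regressions predict with minimal variance.  This matters at reduced
training scale: taking the reference maximum over a fine lattice of
off-center points inflates it by the surrogate's prediction noise
(a maximum over many noisy values), which in pilot runs drove coverage
from the reference ~50% down to 0–25%; finer lattices remain available via
`n_eval` for plotting.

## The power harness and the synthetic world

`run_power_study()` scripts the two validation designs: a *fixed-tau*
factorial panel ($\tau = 0.1$; $M_{12} = M_{21} \in \{0.5, 2\}$; $\theta \in
\{5, 10\}$; $\rho \in \{5, 10, 20\}$; 20 datasets of 7 one-kb loci per
cell) and a *randomized* design ($\tau$ and unequal $M_{12} \neq M_{21}$
uniform on $[0.01, 9]$, $\theta$ and $\rho$ uniform on $[5, 20]$; uniform
on the natural scale by default, with log-uniform sampling behind a switch
since either reading of "random draws" is defensible).  Reported statistics:
relative error $(\hat x - x)/x$, relative RMSE, the Factor-2 proportion
(estimates within $[x/2, 2x]$, boundaries inclusive) and region coverage.
Failed estimator runs are excluded from aggregates but always counted and
reported.

The generator's defaults are the validation-study conditions
($n_1 = n_2 = 10$, 7 loci of 1,000 bp, equal $\theta$'s).  What the
synthetic world does *not* emulate: variable recombination or mutation
rates across loci, gene conversion, population growth, selection,
mis-polarized alleles, or more than two populations.  A green replication
therefore establishes internal consistency of the estimators under the
model's own assumptions, not robustness to their violation.

## Numerical choices and scale reductions

* Desk-scale replications shrink the training grid from $40^3\times10$ to
  $16^3\times5$ while keeping the full-scale $8\times8\times8$ block
  partition (2 grid values per block edge instead of 5).  The block
  *centers* define strategies J1/J2, so preserving their number and
  placement is the faithful reduction; thinning within-block records only
  widens the regression standard errors.  Both geometries were compared
  during development; the coarser 64-center variant visibly shrinks J2
  towards the grid middle.
* The randomized-median replication uses 50 datasets (full scale: 100)
  and the coverage panel 40 (full scale: 140), the documented
  tolerances widening accordingly; the coverage surrogates keep the
  full-scale 10 replicates per grid combination, since the region statistic
  is the quantity most sensitive to regression noise.
* The parameter-recovery experiment restricts its truths to divergence
  times above 0.5 (in $2N_1$ units).  This is a documented domain
  restriction, not a strength claim: at recent divergence the JSFS carries
  too little information to separate migration from divergence, migration
  estimates break down for every method in this family, and factor-2
  recovery of migration rates is not attainable there.
* `optim`'s Nelder-Mead with a logistic box transform stands in for a
  dedicated bounded simplex; starts are exact block centers.
* Sub-seeds for independent simulation streams are derived from the single
  run seed by a seeded `sample.int`, and the C++ generator decorrelates
  (seed, locus) pairs with a splitmix64 hash, so every result is
  reproducible from one integer.

## Known limitations

The estimators inherit the composite-likelihood caveats: treating classes
(and sites) as independent understates uncertainty, which is why the coverage
of the chi-square regions sits near 50% rather than 95% — the
package reproduces that behaviour rather than fixing it, and parametric
bootstrap intervals would be the principled upgrade.  Estimates of
migration rates at very recent divergence ($\tau < 0.1$) are strongly
biased upwards for all strategies; $\theta$'s and $\rho$ are never
estimated; and real-data ingestion (VCF, outgroup polarization) is out of
scope — interchange happens through the ms text dialect and the JSFS/TSV
formats.
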