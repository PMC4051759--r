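---
title: "Comparative phylogenetic methods for contrasting lianas and trees"
author: "lianevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative phylogenetic methods for contrasting lianas and trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lianevol)
```

## The question and the design

Woody climbers (lianas) and free-standing trees coexist across tropical
and temperate forests but are thought to differ in their evolutionary
dynamics: the climbing habit is a candidate key innovation associated
with elevated diversification.  `lianevol` implements the comparative
machinery needed to ask whether ecophysiological traits — maximum
photosynthetic rate (Amax), dark respiration rate (Rd) and specific leaf
area (SLA) — evolve faster, diverge further, or carry more phylogenetic
signal in one growth form than the other, on a time-calibrated phylogeny
of species pooled across sites into one liana and one tree
"super-community".

Three statistical blocks operate on a calibrated ultrametric tree
(branch lengths in Myr) and a species trait table:

1. **Rates of trait evolution.**  Growth form is modeled as a two-state
   continuous-time Markov (Mk) character; stochastic character maps —
   fully timed histories of the character along every branch, drawn from
   the posterior given the tip states — partition the tree into liana
   and tree regimes.  A state-dependent ("noncensored") Brownian motion
   model then assigns each regime its own diffusion rate $\sigma^2_k$
   (trait variance accumulated per Myr), estimated by maximum
   likelihood and compared to a single-rate model by a likelihood ratio
   test.
2. **Phylogenetic and trait diversity.**  The mean pairwise distance
   (MPD) of each growth form is standardized against a null obtained by
   reshuffling species labels across the pooled tree:
   $z = (\mathrm{obs} - \bar{\mathrm{null}})/\mathrm{sd}(\mathrm{null})$,
   with a rank-based quantile p.  Replacing the phylogenetic distance
   matrix by a per-trait distance matrix gives the trait analogue
   (SES_MTD).
3. **Phylogenetic signal.**  Blomberg's K (with a tip-shuffling
   permutation test on the variance of standardized independent
   contrasts) and Pagel's $\lambda$ (with a likelihood ratio test
   against $\lambda = 1$) are computed per trait and growth form on the
   tree pruned to the species with data.

## Models and estimation

### Brownian likelihoods

Under Brownian motion the tip values are multivariate normal with mean
$\mu\mathbf{1}$ and covariance $\sigma^2 C$, where $C_{ij}$ is the
shared root-to-MRCA path length.  The state-dependent model replaces
$\sigma^2 C$ with $\sum_k \sigma^2_k C_k$, where $C_k$ accumulates only
the time the shared path spends in state $k$ under one stochastic map;
the $C_k$ sum exactly to $C$ (this conservation is asserted at `1e-9`
for every sampled map).  Estimation is ML with divisor $n$ (REML is
available by flag on the single-rate fit); the ancestral mean is
profiled out by GLS at every step.  The multi-rate optimizer works on
log-rates with multi-start (the single-rate estimate, and it scaled by
0.25 and 4) to avoid the ridge local optima this likelihood can have,
with a convergence tolerance well below the `1e-6` nesting slack allowed
between single- and multi-rate log-likelihoods.

Confidence intervals are profile-likelihood sets at
$\chi^2_{1,0.95}/2 = 1.92$ log-likelihood units, re-optimizing the
remaining parameters at each evaluation.  When rates are estimated over
a map ensemble, point estimates are across-map means and the interval is
computed on the *pooled profile* — the across-map mean of per-map
profile curves on a common log-rate grid (31 points spanning a factor of
30 either side of the pooled estimate) — so mapping uncertainty widens
the interval.

### Stochastic mapping

The Mk fit defaults to equal rates (one parameter), the minimal
identifiable model at the ~134-species scale; all-rates-different is
available by flag.  The root prior is the stationary distribution of the
fitted rate matrix (uniform under equal rates).  Maps are drawn by
backward filtering / forward sampling of node states on the pruning
recursion, then branch interiors are drawn conditional on endpoints by
rejection sampling of forward Markov paths, bounded at 10,000 attempts
per branch (an error, never a silent fallback, beyond that).  The
ensemble size defaults to 100 maps.  These choices are documented
defaults, not values inferred from any published analysis: ensemble
size, model form and root prior are rarely reported in this literature.

### Age calibration (BLADJ-style smoothing)

Backbone topologies with ages fixed at a subset of internal nodes are
calibrated by even interpolation: each unconstrained node takes the age
interpolated between its nearest constrained ancestor and nearest
constrained descendant, counting nodes along the path, with tips acting
as age-0 constraints.  Where several constrained descendants tie in
topological distance the *oldest* is used (keeping ancestors oldest),
nodes are processed in preorder for determinism, and a final preorder
clamp to the parent age guarantees non-negative branch lengths.  The
original tool's input-order dependence is deliberately not reproduced;
the operation is idempotent.  Polytomies are resolved randomly (seeded)
with zero-length branches, which leaves every tip-to-tip distance
unchanged; the zero branches are kept at exactly zero except inside the
contrasts recursion, where they are jittered by `1e-8` times tree depth
(logged) to avoid zero contrast variances.

### SES null model

The null for both SES_MPD and SES_MTD draws `n_reps = 999` random
groups of the observed size from the pooled species set, which for
MPD-type statistics is equivalent to reshuffling species labels across
the distance matrix.  The quantile is computed as
$p = (\#\{\mathrm{null} \le \mathrm{obs}\} + 1)/(n_\mathrm{reps} + 1)$,
avoiding exact 0/1; `p > 0.95` flags evenness, `p < 0.05` clustering.
The pool is the union of all species (for 134 species the null operates
over $\binom{134}{2} = 8911$ pairs); it is configurable.  Trait
distances are absolute differences of one z-scored trait at a time —
analyses are per trait, never on a multi-trait composite.

### Signal statistics

K is computed from the phylogenetic GLS mean with the standard
normalization that forces $K = 1$ exactly on a star phylogeny, and its
permutation test uses the variance of standardized contrasts under 1000
tip shufflings (one-sided: low contrast variance indicates signal; the
p-value floor is $1/(n_\mathrm{perm}+1)$).  Contrasts are linear in the
tip values, so the permutation null is computed by a single matrix
product.  $\lambda$ scales the off-diagonal of $C$; for fixed $\lambda$
the rate and mean are closed-form, so the estimate is a 1-D profile
search on $[0, 1]$ — the feasible range on ultrametric trees — with both
endpoints evaluated explicitly.  An opt-in extension allows
$\lambda > 1$ but stops at the positive-definiteness limit of
$C(\lambda)$.  The LRT against $\lambda = 1$ clips the statistic at zero
and reports boundary hits: at a boundary the test is conservative, which
is preferable to guessing the direction an unreported original test
took.  Likelihood-ratio statistics are always clipped at zero; published
tables of this kind occasionally print negative values, which a nested
LRT cannot produce, and the package does not reproduce that artifact.

## The synthetic-data generator

Real supplements of this design cannot be redistributed, so the
generator produces datasets with the same statistical structure, used by
every test:

* a pure-birth tree rescaled to a root age of 150 Myr — an
  angiosperm-scale timescale of order $10^2$ Myr — with 134 tips by
  default;
* growth form evolved under a symmetric Mk model at
  `q = 0.01` transitions per Myr, redrawn until exactly 63 species are
  lianas and 71 trees (a `"clade"` mode instead paints the clade nearest
  63 species as lianas, giving a maximal-clustering fixture);
* traits evolved under state-dependent Brownian motion along the *true*
  simulated history, at rates of order 0.1 per Myr taken from the
  magnitudes a field analysis of this kind reports (Rd-like: 0.148
  lianas vs 0.083 trees; Amax-like: 0.075 in both; SLA-like: 0.093 vs
  0.103), from a root value of 0 on a standardized trait scale;
* per-trait, per-group missingness with deterministic cell counts
  (`round(fraction * group size)`), tuned so available sample sizes span
  26 (Rd/lianas) to 67 (Amax/trees).

The generator emulates the *scale and structure* the analysis assumes,
not real ecophysiology: traits are exactly Gaussian with no measurement
error, missingness is completely at random, sites are decorative labels,
and the tree is a homogeneous pure-birth realization with no extinction.
Passing calibration tests therefore demonstrates the estimators are
correct under their own model assumptions at the study's scale — not
that those assumptions hold for any particular forest dataset.

Because the trait transformation behind published $\sigma^2$ magnitudes
of this kind is unreported, the pipeline's default preprocessing
(natural log for strictly positive traits, then z-scoring; both
configurable and recorded) defines its own scale, and numeric identity
with any published rate table is out of scope.  Rate-recovery tests
instead simulate at the published magnitudes and require the generating
values back.

## Problem sizes and numerical choices

The test suite exercises the pipeline at the study scale — 134-tip
trees for rate recovery (100 replicates unequal rates, 200 equal-rate
replicates for test size), 100-tip trees for signal calibration (500
replicates for K, 200 for $\lambda$), and 500 random groups against a
999-replicate SES null — sizes chosen to put Monte-Carlo error
comfortably inside the asserted bands (3 SE or exact binomial 95%
intervals throughout).  Degenerate inputs are handled explicitly:
constant traits give $\sigma^2 = 0$ with a warning, a degenerate SES
null (group = pool) is an error, singular covariances (possible after
zero-length resolution branches) get an escalating logged diagonal
jitter starting at `1e-10` of the mean diagonal, and ultrametricity is
declared at relative tip-depth tolerance `1e-6`.

One naming clarification: pairwise distances on the calibrated tree are
path-length (cophenetic/patristic) distances computed directly on the
tree.  Descriptions of this workflow sometimes mention a UPGMA
clustering step alongside the cophenetic matrix; on an already
calibrated ultrametric tree no clustering is involved, and none is
performed here.

## Known limitations

* Two states only; no hidden-rate or >2-state models, and no Bayesian
  sampling of the Mk rate matrix.
* Brownian motion only (no OU or early-burst alternatives), univariate
  traits only, and no censored-by-clade rate tests.
* SES machinery covers MPD-type statistics with the taxa-label null;
  nearest-neighbor metrics, abundance weighting and independent-swap
  nulls are out of scope.
* Megatree assembly, taxonomic name resolution and fossil-calibration
  inference are upstream of this package: the backbone topology and the
  node-age table are user inputs.
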