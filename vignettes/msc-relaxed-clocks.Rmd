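---
title: "The multispecies coalescent with relaxed molecular clocks: model, sampler, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The multispecies coalescent with relaxed molecular clocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coalclock)
```

## The model

A rooted species tree for `s` species carries divergence times `tau` (node
ages, expected substitutions per site, tips at 0) and mutation-scaled
population sizes `theta = 4*N*mu`, one per branch including the stem above
the root, which extends indefinitely.  Given the species tree, each locus
has its own genealogy: within every population, each pair of lineages
coalesces at rate `2/theta`, lineages that reach the top of a population
continue into its parent, and everything that remains coalesces in the root
population.  The density of a gene tree with its coalescent times therefore
factorises over populations into exponential waiting-time terms and
survival terms, and that factorisation is exactly how both the density
code and the forward sampler are organised.  Incomplete lineage sorting —
coalescence in an ancestor older than the species split — is governed by
internal branch lengths in *coalescent units*, `2 * duration / theta`; the
bundled four-species example tree has an internal branch of only 0.2
coalescent units, which is why it is a hard tree to recover.

Substitution rates vary on two axes.  Across loci, locus `i` has an overall
rate `mu_i` and, under relaxed clocks, a rate-variance parameter `nu_i`
saying how strongly the clock is violated at that locus.  Across species,
each species-tree branch `j` gets a rate `r_ij` at locus `i`; a gene-tree
branch may cross several populations, and its length in substitutions is
the sum over crossed populations of residence time times that population's
rate (the segment decomposition).  Three clock models are supported:

* **clock 1** — strict: `r_ij = mu_i` everywhere;
* **clock 2** — independent rates: the `2s-1` branch rates (root stem
  included) are i.i.d. around `mu_i`, with either a gamma kernel
  `G(mu^2/nu, mu/nu)` (mean `mu`, variance `nu`) or a log-normal kernel
  whose log-mean carries the `-nu/2` correction so the *rate* mean is
  `mu_i` (the variance is then `(e^nu - 1) mu^2`);
* **clock 3** — correlated rates: daughter-branch rates are generated
  recursively from the mother-branch rate in a pre-order pass; the root
  stem uses `mu_i` itself, so clock 3 has exactly `L` fewer free rates
  than clock 2.

Note that `nu` means different things under the two kernels (a rate
variance under the gamma, a log-rate variance under the log-normal) and
under clocks 2 and 3 (marginal spread vs diffusion speed); estimates are
comparable only within one setting.

### The correlated log-normal covariance

The geometric-Brownian-motion variant of clock 3 needs a concrete
covariance, which we document here because the construction leaves a
choice.  Rates live at branch midpoints.  For an internal node whose
parent branch has duration `Da` and whose daughter branches have durations
`D1`, `D2`, the two daughter log-rates given the parent midpoint log-rate
are bivariate normal with variances `nu * (Da + Dk) / 2` and covariance
`nu * Da / 2` — the shared part of the Brownian path is the
parent-midpoint-to-node segment.  Each conditional mean is shifted down by
half its variance so that `E(daughter rate | parent rate) = parent rate`.
As the daughters' durations shrink the correlation tends to 1, as it
should.  Because the root stem is infinite it has no midpoint; we treat
`mu_i` as the rate *at the root node*, so the root's daughters share no
segment and are conditionally independent.  This is the one place where a
different, equally defensible convention (e.g. an imagined root stem of
fixed length) would change the density; the choice is isolated in one
function and covered by sampler-vs-density tests.

### Priors

The root age takes a gamma or inverse-gamma prior; the other node ages are
uniform over their order-constrained region given the root age, and the
normalising constant of that region (the number of linear extensions of
the internal-node partial order, computed exactly for the small trees in
scope) is included so that root-age marginals and cross-topology moves are
exact.  Each `theta` takes an inverse-gamma, gamma, or bounded beta prior;
the beta's hard bounds are enforced by rejection (`-Inf`, never an
exception).  Per-locus `mu_i`/`nu_i` take either the conditional i.i.d.
prior — `G(alpha, alpha/mean)` around a shared mean with its own gamma
hyperprior — or the gamma-Dirichlet, in which the *total* across loci is
partitioned by a Dirichlet with concentration `alpha`.  With the mean
overall rate fixed at 1 (the convention throughout: no fossil
calibrations, so times are in substitutions per site), the gamma-Dirichlet
for `mu` degenerates to the scaled simplex `sum(mu_i) = L`, and the
sampler's pairwise-transfer proposal preserves that constraint exactly.
Substitution models (JC, K80, HKY, GTR, optionally with discrete-gamma
among-site variation using category means, 5 categories by default) take
uniform Dirichlet priors on frequencies and exchangeabilities and a gamma
prior on the shape.

## The sampler

`mscfit()` runs a Metropolis–Hastings sweep over: gene-tree node ages
(sliding windows bounded below by the floor of the node's population, a
multiplier for the unbounded gene root), gene-tree topology
(prune–regraft among lineages contemporaneous with the chosen node and in
the same population, which makes the candidate set identical in both
directions and the Hastings ratio 1), species divergence times with the
rubber-band rescaling (coalescent times inside the affected populations
map affinely onto the new interval; only internal gene nodes enter the
Jacobian — tips are pinned at age 0), population sizes, `mu_i`/`nu_i` and
branch rates (multipliers; pairwise transfers under the fixed-mean
gamma-Dirichlet), hyper-means, substitution parameters
(Dirichlet-neighbourhood proposals for frequency and exchangeability
vectors, multipliers for shape and kappa), and two whole-state scale
moves: one rescales all times and thetas together, the other rescales
times *and* rates in opposite directions so that every branch length —
and hence the likelihood — is left unchanged, which decorrelates the time
scale from the locus rates (the variance parameters transform with the
exponent that preserves each kernel's shape: −2 for the gamma kernels, 0
for the independent log-normal, −1 for the geometric Brownian motion).
A per-locus analogue multiplies `mu_i` jointly with that locus's whole
branch-rate vector, which the correlated log-normal density is
shape-invariant under and which removes the slowest-mixing direction of
the clock-3 chains; a further hierarchical move rescales `nu_bar` together
with all `nu_i`, the level of the variance hierarchy that single-site
multipliers explore only by a slow random walk.
Step sizes are tuned toward roughly 30% acceptance during burn-in and then
frozen, so the retained sample is from an exact MH chain.  Caches of the
per-locus coalescent density and pruning likelihood are maintained per
move; a debug mode recomputes everything from scratch every sweep and
stops on any disagreement, and that mode runs in the test suite.

With `search = TRUE` the species tree itself is sampled through rooted
NNI moves.  Divergence times, thetas and per-locus branch rates stay
attached to their nodes, so they transfer by branch identity (the clade
under a node changes, its parameters do not), which changes gene-tree
branch lengths — and the likelihood — even for gene trees that need no
rearrangement.  Gene-tree nodes whose child lineages no longer share a
population at the node's age are pruned and regrafted at the same age
onto a uniformly chosen lineage of the right population; the proposal
probability of the realised rearrangement is computed by summing over all
choice paths that produce it, in both directions, so the Hastings ratio
is exact.  A prior-only search on three species visits the three rooted
topologies uniformly, which is a sensitive end-to-end check of this
machinery.  Tree search is intended for small trees (roughly `s <= 6`):
the trans-model move carries many rate parameters and mixes slowly under
relaxed clocks, markedly so under the correlated-rates model, where
results for more than a few dozen loci should be treated as unreliable —
`mscfit()` warns accordingly.  Parameter estimation on a fixed tree does
not suffer from this.

## The simulator

`simulate_dataset()` (or `simulate()` on an `msc_model`) follows the
generative process exactly: gene trees under the coalescent, rates under
the clock model, branch lengths by the segment decomposition, sequences
down the gene tree under per-locus substitution parameters drawn from
their priors (defaults: frequencies `Dir(10,10,10,10)`, exchangeabilities
`Dir(10,5,5,5,5,10)` — prior mean transition/transversion ratio 2 — and
shape `G(2,2)` with 5 categories).  Simulation and inference share one
discrete-gamma implementation and one pruning implementation, so the
simulator is exactly the model the sampler assumes.  Every latent variable
is recorded for parameter-recovery studies.  What the generator does *not*
emulate: alignment error, indels, selection, gene flow, rate correlations
across loci (lineage effects).  Tests that pass on these data therefore
validate the implementation of this model, not the model's adequacy for
any particular empirical system.

## Validation harnesses

Two harnesses mirror standard sampler-validation practice.
`prior_check()` fixes the likelihood at 1 and compares every sampled
marginal with its analytic prior by the sup-distance between CDFs, with a
tolerance scaled by the chain's effective sample size.
`bayesian_simulation()` draws parameters from the prior, simulates data,
samples the posterior, and checks that the posterior *averaged over
replicates* recovers the prior for every monitored quantity — including
the latent gene-tree height and length, whose priors are estimated by
forward simulation.  The decision statistic is the calibration rank: the
rank of each replicate's true value within its own posterior draws is
exactly uniform under a correct sampler at any replicate count, so the
per-quantity Kolmogorov statistic of the ranks carries an exact
finite-sample familywise band.  The replicate-averaged CDF against the
forward prior, with a cluster-bootstrap z-score, is also reported as a
diagnostic — at a handful of replicates that comparison mostly reflects
which truths happened to be drawn, which is why it does not decide the
outcome.  No formal significance test of "correctness" is attempted,
since at small replicate counts a non-rejection would mostly measure its
own lack of power.  The
harness also runs a negative control: dropping the `-nu/2` term from the
log-normal rate density on the inference side only must produce a flagged
discrepancy, otherwise the harness itself is too blunt.

## Problem sizes and numerical choices

The defaults used in the package's own test suite and acceptance script
are deliberately small: a three-species tree with one or two sequences
per species, 2–10 loci of 100–300 sites, prior-recovery chains of a few
thousand sweeps, Bayesian-simulation runs of 10–20 replicates, and a
parameter-recovery study of about a dozen replicates of 8 loci — sizes
chosen so the whole battery runs on a single CPU in minutes while leaving
each check enough resolution to fail visibly when a density or proposal
is wrong (the injected-bug control demonstrates that).  Full-scale
studies (hundreds of replicates, hundreds of loci) use the same code
paths with larger settings.

Other choices worth recording: node ages are absolute (tips at 0) and
branch lengths always derived; internal nodes are addressed by their
descendant tip sets so parameters survive topology changes; proposals out
of support are rejected via `-Inf` log densities rather than exceptions;
gaps and IUPAC ambiguities enter the likelihood as partial likelihoods of
1 over compatible states and are never stripped; the discrete-gamma uses
category means; ties in MAP-topology counting break by first occurrence.
The pruning likelihood and the per-locus evaluation (embedding, segment
lengths, coalescent density) are implemented in C++ for speed, and the R
reference implementations of the same quantities remain in the package
and are tested against the C++ path.

## Limitations

Gene flow and introgression are outside the model; analytic integration
of `theta` under the conjugate inverse-gamma prior is not performed (all
`theta`s are sampled explicitly, uniformly across the three prior
families); species-tree search is NNI-only and practical only for small
trees; and rate evolution is independent across loci, so strong lineage
effects in real data will be absorbed into branch rates rather than
modelled.
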