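---
title: "Tip dating with linked fossil-site ages and stratigraphic ordering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tip dating with linked fossil-site ages and stratigraphic ordering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratatips)
```

## The problem

In Bayesian tip dating, fossil taxa enter the phylogenetic analysis as dated
terminals. The age of a fossil is rarely known exactly; the usual remedy is a
uniform prior on each tip's age across its stratigraphic uncertainty window.
Applied tip by tip, this has an unwanted consequence: fossils collected from
one locality — sometimes literally from one block of rock — are free to drift
millions of years apart in the posterior, because nothing in the model says
they share an age. A second, related problem is that fossil-bearing layers in
one stratigraphic section have a known vertical ordering even when their
absolute age windows overlap entirely; per-tip uniform priors cannot express
"A lies below B".

`stratatips` addresses both with two Metropolis–Hastings proposals on tip
ages:

* **Linked site ages.** All tips belonging to one fossil site share a single
  age parameter. A proposal draws one age uniformly within the site's bounds
  and applies it to every tip of the site simultaneously. The draw is
  symmetric, so the Hastings ratio is 0.
* **Stratigraphic ordering.** When sites form a sequence, a proposed site age
  that would invert the sequence — older than the current age of a site below
  it, or younger than a site above it — is rejected outright (equivalently,
  assigned prior probability zero). The admissible window for each site thus
  depends on the current ages of its neighbours and moves as the chain runs.
  Exact ties are allowed; under continuous proposals they occur with
  probability zero, and tolerating them avoids spurious rejections when two
  sites share a degenerate bound.

Taxa not assigned to any site receive an individual single-taxon site, which
makes the conventional "independent tip ages" analysis a special case
(`linked = FALSE` explodes every multi-taxon site this way; it also discards
ordering relations, which are defined between sites).

An important consequence of ordering, and the reason prior-only runs matter:
the *effective* prior on an ordered site's age is no longer uniform. For two
sites with identical bounds, the joint effective prior is uniform on the
ordered triangle, so the lower site's marginal is the distribution of the
maximum of two iid uniforms (mean at 2/3 of the window) and the upper site's
the minimum. `run_chain()` exposes this directly: `prior_only = TRUE` replaces
the likelihood with a constant, and `fix_tree = TRUE` additionally freezes the
topology and internal-node ages and omits the tree prior, isolating the
operator-induced prior so it can be compared against the independent
rejection-sampling oracle (`rejection_sample_site_ages()`).

## The model stack

The proposals are exercised inside a deliberately minimal but complete
Bayesian tip-dating model:

* **Likelihood.** Lewis's Mk model for discrete morphology, with per-character
  state counts taken from the observed states, uniform stationary root
  frequencies, and optional conditioning on characters being variable (Mkv).
  The conditioning divides each character's likelihood by one minus the
  probability of a constant pattern, computed with the same branch lengths and
  rate mixture and that character's state count; by the state symmetry of Mk
  this probability is `k` times the probability that all tips show state 0.
  Missing cells contribute partial likelihood 1 in every state.
* **Among-character rates.** A discrete gamma mixture (default 4 categories).
  Category rates are the means of equal-probability bins of
  Gamma(shape, rate = shape) — the mean-of-bin rule rather than median-of-bin,
  because it normalises exactly to mean 1 and so keeps tests deterministic.
* **Clock.** An uncorrelated lognormal relaxed clock: each branch carries an
  iid lognormal multiplier with mean 1 in real space and sdlog equal to the
  clock standard deviation parameter. Multipliers are continuous, not
  discretised into categories; the site-age proposals do not interact with
  this choice.
* **Tree prior.** A serially-sampled birth-death process conditioned on the
  origin age, with birth rate λ, death rate μ and fossil-sampling rate ψ.
  Sampling removes the sampled lineage, which is exactly the model in which
  every sample is a terminal tip and sampled ancestors cannot arise — matching
  the package's strictly binary, strictly positive-branch trees. Tips at age 0
  are sampled with probability 1. The origin age carries an improper uniform
  prior above the root age.
* **Hyperpriors** (all defaults): clock rate, exponential with mean 0.003
  offset by 0.0016 (substitutions/character/Ma); clock standard deviation,
  exponential with mean 1; gamma shape, Uniform(0, 10); birth rate, lognormal
  with mean 0.14 in real space and sdlog 0.9 (per Ma); death rate, exponential
  with mean 0.1; sampling rate, exponential with mean 0.03. "Mean in real
  space" is resolved as `meanlog = log(m) - sdlog^2/2`.

Ages are in Ma before the present and increase into the past; "younger" means
numerically smaller.

## The operator set

Beyond the two site-age proposals, the chain uses a standard set: a uniform
slide of an internal node age between its oldest child and its parent; scale
moves (factor uniform on `[1/β, β]`, Hastings `-log f`, β = 1.25) on the
scalar rates; narrow exchange for topology; a log-scale random walk on single
branch-rate multipliers; and additive/uniform moves on clock rate and gamma
shape (a bounded parameter mixes far better under an occasional uniform
redraw than under multiplicative steps). Root and origin ages are updated by
scaling the *gap* above the oldest child (respectively above the root) rather
than the absolute age — scaling a ~415 Ma number directly would essentially
never be accepted.

One non-obvious operator deserves note. The clock standard deviation and the
branch-rate multipliers form a funnel: small sd forces all multipliers to 1,
and componentwise moves cannot descend into or climb out of that region at a
useful rate, which visibly distorts the sampled sd marginal in prior-only
runs. The package therefore includes a non-centered joint move: it rescales
sd while holding fixed the standardized latents
`z_i = (log m_i + sd^2/2) / sd`, transforming the multipliers accordingly and
accounting for the full Jacobian in the Hastings ratio. With the latents
fixed the acceptance under the prior depends only on the sd prior, so the
move can take large steps (factor up to 4).

Tip-age proposals that would place a tip at or above its parent's age are
hard-rejected rather than dragging the parent — the same rejection semantics
as the ordering constraint, with a much simpler correctness argument.

Operator weights: each site operator is weighted by its taxon count (sites
with degenerate bounds get weight 0 — the proposal would be a no-op); the
standard moves carry fixed documented weights (see
`stratatips:::default_std_weights`). Weights can be overridden per-analysis
via `analysis_config(weights = ...)`, which the test suite uses to isolate
single operators.

## Initialisation and numerics

* Initial site ages sit at bound midpoints, adjusted along stratigraphic
  chains (via longest-path depths in the relation graph) so ordering holds
  from the start; a starting tree, when not supplied, is built by randomly
  joining subtrees above the tip ages with exponential gaps. A state with
  zero prior probability is reported as an error naming the offending
  component, never sampled from.
* The pruning likelihood rescales partials per node only when they underflow
  (threshold 1e-200), accumulating the log correction.
* The birth-death density is evaluated through `log q(t)` directly in log
  space; the validity of the closed form is tested against an independent
  numerical integration of the process ODEs.
* Proposals are evaluated prior-first: a structurally invalid or
  out-of-support state is rejected before the likelihood is touched.
* The posterior, likelihood and prior columns of the trace satisfy
  `posterior = likelihood + prior` to 1e-8 at every logged row; the prior
  column includes the tree prior, the hyperpriors, the branch-rate density
  and the (constant) site-age uniform terms.

## What the synthetic data emulate — and what they do not

`simulate_bdss_tree()` runs the same birth-death-sampling process forward
(sampling removes the lineage) and prunes to sampled tips, so simulated trees
are draws from the tree prior's generative counterpart; this is checked by
comparing simulated root-age distributions against the normalised closed-form
density on small cases. `simulate_mk_matrix()` evolves characters under the
same Mk process (per-character rates drawn from the discrete-gamma
categories, strict clock), with constant characters optionally resimulated to
emulate Mkv-style ascertainment — by resimulation, not reweighting, so it
matches the conditioned data-generating distribution exactly.

`make_fixture_dataset()` assembles a study-shaped scenario: a fossil tree of
14–30 taxa (10–16 in the replicated precision study, which trades tree size
for seed count) spanning the late Silurian–Early Devonian, two four-taxon
fossil sites whose member tips share an exactly common true age, both sites
carrying the identical Lochkovian uncertainty window (410.8–419.2 Ma) in a
two-site ordered sequence, remaining fossils given ±2 Ma independent windows,
and ~50–100 binary/ternary characters at a clock rate of 0.005
substitutions/character/Ma — fast enough that a desk-scale chain is
measurably informed about tip ages, and in the range a morphological matrix
with autapomorphies can plausibly support. Simulated matrices are missing
10% of cells uniformly at random.

What passing tests on these fixtures show is that the machinery is correct
and that linking demonstrably sharpens site-age estimates *when the linked
model is true and characters are clock-like*. Real morphological data violate
several of these assumptions at once (non-clock-like rates, correlated
characters, non-random missingness, ordered multistate codings, polymorphic
codings — the latter two are rejected by the reader rather than approximated),
so effect sizes on real data will differ even where the direction of the
effect is expected to hold.

## Problem sizes used by the checks

The validation suite runs, among others: prior-only chains of 10^6
generations (thinned to ~10^4 samples) for the effective-prior and
hyperprior-reproduction checks; brute-force likelihood enumeration on all
trees up to 4 tips and 3 states; and a ten-seed replication of the precision
study, each seed comparing a linked and an independent 10^6-generation
analysis of a ~12-taxon, 50-character fixture. These sizes were chosen so
the full suite completes on one CPU in well under half an hour while leaving
each statistical check with comfortable Monte-Carlo headroom; the acceptance
script (`scripts/acceptance.R`) repeats the same computations at five seeds
for the precision study.

## Known limitations

* Sampled ancestors are out of scope by design: trees are strictly binary and
  every branch strictly positive. Datasets where fossils are plausibly direct
  ancestors need the sampled-ancestor machinery this package deliberately
  omits.
* Stratigraphic *ranges* (a taxon spanning several layers) are not modelled;
  a site is a single horizon with one true age.
* The ordering prior is purely combinatorial. It assigns zero probability to
  inversions and nothing else — in particular no sedimentation-rate
  information, so two adjacent layers may sit arbitrarily close in age.
* Convergence diagnostics are limited to effective sample sizes and
  acceptance-rate bookkeeping; for production analyses, standard external
  trace diagnostics remain advisable.
* The consensus summary reports topology and clade frequencies only; node
  ages are summarised from the trace, not annotated onto the consensus tree.

## A worked micro-example

```{r example, eval = FALSE}
fx <- make_fixture_dataset(seed = 1, dir = tempfile("demo"))
cfg <- read_config(fx$config_path)
cfg$chain_length <- 2e5
res <- run_chain(cfg, list(matrix = fx$matrix, sites = fx$sites, seq = fx$seq))
post <- discard_burnin(res)
summarize_trace(post$trace[c("age_site_lower", "age_site_upper")])
prob_younger(post$trace$age_site_upper, post$trace$age_site_lower)
```
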