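---
title: "Two-stage occupancy models for eDNA surveys with false positives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage occupancy models for eDNA surveys with false positives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model and its assumptions

An eDNA survey observes, for each of `S` sites, `M` field samples per
site, and per sample the number `y` of `K` qPCR replicates that
amplified. `ednafp` models this as a three-level hierarchy with error at
both observation stages:

* `z_i ~ Bernoulli(psi_i)` — the site is occupied or not;
* `a_ij | z_i ~ Bernoulli(theta11_i)` if occupied, `Bernoulli(theta10_i)`
  if not — the field sample does or does not carry target DNA. `theta10`
  is the stage-1 false-positive probability (field contamination,
  transport of DNA from elsewhere);
* `y_ij | a_ij ~ Binomial(K, p11_i)` if the sample carries DNA,
  `Binomial(K, p10_i)` if not — each replicate amplifies independently.
  `p10` is the stage-2 false-positive probability (lab contamination,
  non-specific amplification).

The assumptions this encodes: occupancy is closed over the sampling
period (all samples drawn at one visit); samples are exchangeable given
`z`; replicates are exchangeable given `a`; and a sample is either
"positive" or "negative" as a whole, so DNA concentration enters only
through the dichotomous capture state. Replicate counts, not individual
well outcomes, are sufficient under these assumptions, which is why the
data model stores `y` and `K` only. `K` may differ between samples
(failed replicates are simply dropped from `K`).

Each of the five probabilities can be a logistic regression on site
covariates. The "baseline site" has all continuous covariates at 0 and
binary covariates at level 0, so baseline probabilities are
`plogis(intercept)`; all probability-scale summaries of a covariate fit
refer to that baseline.

Two derived quantities matter in practice. The conditional absence
probability `P(z = 0 | y = x)` for a single sample with `x` of `K`
replicates amplifying follows from Bayes' rule on the two branches of
the site marginal likelihood; under the identifiable orientation it is
non-increasing in `x`, near its prior `1 - psi` at small `x` relative to
the false-positive rate, and flattening once `x` is decisive. The naive
occupancy rate — the fraction of sites with at least one sample meeting
a replicate threshold — is the model-free comparator.

## Identifiability and priors

With replication at both stages, all five probabilities are identified
by the data. Without field replication (`M = 1`, the common commercial
protocol) the likelihood only identifies the compound
`psi * theta11 + (1 - psi) * theta10` together with `p11`, `p10` and the
sample-positivity rate: occupancy and stage-1 capture cannot be
separated. Three devices can restore separation, and the package
supports all of them: confirmed presences (direct observations fixing
`z_i = 1`), covariates on the probabilities, and informative priors.

The default priors are therefore deliberately informative everywhere
except occupancy:

| parameter | default | reasoning |
|---|---|---|
| `psi` | Beta(1, 1) | occupancy is the estimand; left flat |
| `theta11`, `p11` | Beta(8, 2) | a deployed protocol/assay is validated; sensitivity is known to be high before any survey data arrive. Mean 0.8, prior weight of ten observations |
| `theta10`, `p10` | Beta(1, 19) | false positives are real but rare; mean 0.05 concentrated near zero |
| coefficients | Normal(0, 1.5²) | weakly informative on the logit scale |

The informative true-positive priors deserve a note, because they are a
genuine design choice. Concentrating only the false-positive
probabilities near zero is not enough to make single-sample designs
useful: along the `psi`–`theta11` ridge the posterior of `psi` then
remains essentially as wide as its prior, and design studies comparing
`M = 1` against `M = 2` would measure the prior, not the survey. Survey
planning for a validated assay legitimately knows more than that —
assay validation experiments bound the true-positive rates well away
from coin-flipping — and encoding that knowledge with a prior weight of
about ten observations lets the data dominate as soon as there is real
replication, while keeping `M = 1` designs informative. Both the
equivalent-sample-size and the means are configurable through
`prior_spec()`; conclusions about weakly replicated designs should
always be read as conditional on these priors, and a sensitivity check
with flatter true-positive priors is cheap. The covariate-model
intercepts use the same Beta priors transported through the logit link
(density transformed with the logistic Jacobian), so covariate-free and
covariate fits encode the same marginal beliefs.

## The sampler

Fitting is by data augmentation. Each sweep:

1. draws every `a_ij` from its Bernoulli full conditional given
   `(z_i, y_ij)`;
2. draws every `z_i` from its Bernoulli full conditional given the
   site's `a` values (confirmed-presence sites stay at 1), with the
   branch log-masses accumulated in log space;
3. updates the probabilities. Covariate-free probabilities have
   conjugate Beta full conditionals. The orientation constraint
   `theta11 > theta10` (and `p11 > p10`) is part of the prior: the pair
   is redrawn jointly until ordered, which samples the truncated joint
   full conditional exactly (capped at 200 attempts, after which the
   previous values are kept — in practice unreachable). Covariate-bearing
   probabilities update their coefficient vectors by random-walk
   Metropolis, two proposals per sweep, with the proposal scale adapted
   during burn-in toward a 0.3 acceptance rate (Robbins–Monro on the log
   scale); if either member of a stage pair carries covariates, both
   members use Metropolis so the constraint applies coherently through
   their intercepts.

Posterior summaries report probability-scale parameters (at the
baseline site), logit-scale coefficients when present, 95% credible
intervals as 2.5%/97.5% quantiles, and per parameter an
autocorrelation-based effective sample size and split-R̂. Per-site
occupancy is stored at every kept draw as the Rao-Blackwellised
`P(z_i = 1 | y_i, params)` — the latent states are marginalised at the
current parameters — which gives smooth site summaries even from the
short default runs.

The default run length (1 chain, 1000 burn-in, 2000 iterations, thinning
10, so 200 stored draws) matches the study protocol this package
replays and is adequate for the well-identified designs; for reporting
on real data, longer chains (and 2+ chains, supported via `n_chains`)
are recommended, using the reported ESS/R̂ as the guide.

The constrained no-false-positive variant fixes `theta10 = p10 = 0`.
Any amplifying replicate then forces its sample positive and its site
occupied, which is exactly how the conventional multi-scale occupancy
model reads such data; the contrast between the two fits
(`compare_models()`) measures the cost of that reading when low-level
false positives exist.

## What the simulator emulates — and what it does not

`simulate_dataset()` draws from precisely the hierarchy above, with
default study conditions copied from the survey context the package
targets: sparse occupancy (`psi = 0.1`), sensitive stages
(`theta11 = 0.85`, `p11 = 0.9`), rare false positives
(`theta10 = p10 = 0.01`), and two site covariates — one continuous,
standard normal (the "centred at zero" choice made concrete with unit
variance, matching the convention of standardising covariates before
analysis), one binary with occurrence probability 0.5. When parameters
are given on the probability scale the covariates are decoys with zero
effect, present only so that single-sample designs retain the covariate
identification device; non-zero effects require
`covariate_model_params()`. Confirmed presences are never generated by
default, since the design studies do not assume them.

Real eDNA data violate the simulator in known ways: DNA concentration
(and hence per-replicate amplification probability) varies continuously
with abundance, inhibition and degradation censor samples
non-randomly, false positives can be spatially clustered
(cross-contamination within batches), and occupancy may change between
samples. Passing tests therefore demonstrate correctness of the
machinery under the stated hierarchy, not robustness to these
violations.

## The replication-design study

`run_design_grid()` sweeps `(S, M, K)`; per cell it simulates `repeats`
datasets, fits the full model to each, and averages per parameter the
bias (posterior mean − truth; positive means over-estimation) and the
95% PCI width. The full study grid is S ∈ {20, 100, 500, 1000},
M ∈ {1, 2, 4}, K ∈ {2, 4, 6, 8, 10, 12} with 10 repeats — 720 fits;
cells are checkpointed to a JSON-lines ledger and keyed by
deterministic per-cell seeds, so the grid is resumable and
order-independent (and embarrassingly parallel). Grid fits include both
decoy covariates on all five probabilities, the uniform protocol that
keeps the M = 1 cells in the same model family as the rest.
`pci_reduction()` then answers the planning question directly: how much
does a second (or fourth) field sample narrow the occupancy interval at
given S and K?

Test and acceptance runs use desk-scale slices of this design — 5
repeats of the S = 1000, M = 4, K = 12 recovery experiment, and the
four cells behind the M 1→2 (S = 500, K = 6) and M 2→4 (S = 20, K = 2)
precision comparisons at 10 repeats — sizes chosen so the whole suite
replays in minutes on one core while keeping Monte-Carlo error visibly
smaller than the tolerances being checked.

## Numerical choices

* Dataset-level likelihoods accumulate per-site log marginals with a
  two-term log-sum-exp; per-site values may be returned on the
  probability scale.
* Zero-probability branches (`psi` ∈ {0, 1}, zero false-positive rates)
  propagate as `-Inf` log-masses and produce exact 0/1 conditional
  draws rather than NaNs; the conditional absence probability returns
  `NA` only for outcomes of probability zero.
* Seeds: every sub-task (grid cell, repeat, chain) derives its seed via
  a 31-bit multiplicative-congruential hash of the base seed and the
  task key (`derive_seed()`), chosen so products stay below 2^53 and
  the modulus is exact in doubles. Simulation restores the caller's RNG
  state.
* Covariate standardisation uses the sample (n − 1) standard deviation
  and records centre/scale for back-transformation; columns with values
  in {0, 1} are detected as binary and left alone. Constant continuous
  covariates are an error, named.
* Identifiability orientation is enforced strictly (`>`), ruling out
  the exactly-degenerate `theta11 = theta10` case at construction;
  degenerate-limit behaviour is tested by approach within `1e-9`.

## Known limitations

* With `M = 1` and only decoy covariates, occupancy remains
  prior-sensitive however large S is: the posterior of `psi` (and of
  derived quantities such as the absence curve's plateau) then reflects
  the true-positive priors as much as the data. The package warns in
  exactly this situation. Precision comparisons involving
  single-sample cells inherit that sensitivity, and at 10 repeats the
  between-run spread of a PCI-width reduction estimate is itself of the
  order of ±10 percentage points.
* The sampler is plain R, vectorised per sweep; a fit of 3000 sweeps at
  S = 1000, M = 4 takes a few seconds. Grids far beyond the study grid
  would warrant a compiled inner loop.
* Replicate-level covariates (e.g. per-plate effects) and continuous
  quantification (Cq values) are out of scope by design; the model
  consumes binary replicate outcomes only.
* Bayesian variable selection over covariates is not provided; designs
  are user-specified.
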