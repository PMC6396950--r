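---
title: "Poisson mixtures under slow promoter kinetics: model, reduction, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Poisson mixtures under slow promoter kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spkmix)
```

## The model

`spkmix` analyzes stochastic gene regulatory networks (GRNs) built from
*gene expression blocks*. A block is a single-copy gene whose promoter
carries up to two transcription-factor (TF) binding sites. Its reactions
are:

* **gene reactions** (slow): TF binding `TF + D_j -> D_j'` at per-copy rate
  `alpha`, unbinding at `alpha_-`; a constitutive promoter instead switches
  autonomously between an inactive and an active configuration;
* **protein reactions** (fast): production `D_j -> D_j + X` at the
  configuration-dependent rate `k_j` (transcription and translation lumped,
  justified by fast mRNA turnover), decay `X -> 0` at `k_-`, and, for a TF
  with cooperativity index `n > 1`, reversible n-merization
  `n X <-> X_c` at rates `beta`, `beta_-`;
* optionally **diffusion** (fast): reversible transport `X_i <-> X_j` at a
  rate `Omega`, modeling protein exchange between communicating cells.

Slow promoter kinetics (SPK) — the regime relevant when binding and
unbinding are modulated by chromatin remodeling or DNA methylation — is
modeled by multiplying every gene-reaction rate by a small parameter
`epsilon`. The package scales *only* the gene reactions by `epsilon` and
leaves protein rates untouched. Stationary distributions are invariant
under a global rescaling of time, so this one-knob convention is
stationarily equivalent to also speeding the protein reactions up by
`1/epsilon`; it keeps a single time unit (the protein scale) throughout.

The state of the chain is `(d, x)`: `d = (d_1, ..., d_N)` collects the
promoter configurations (`L = prod |B_i|` possibilities), `x` the protein
and multimer copy numbers. The chemical master equation (CME) generator
splits as `Lambda_eps = Lambda_tilde + epsilon * Lambda_hat`, with
`Lambda_tilde` block-diagonal over `d`: at `epsilon = 0` each promoter
configuration carries its own autonomous protein process.

## The reduction

Frozen at a configuration `d`, the protein processes are independent
birth–death chains (plus reversible n-merization and transport), and their
stationary law is an exact product of Poissons: the monomer of gene `i` has
mean `a_i = k_{i,d_i}/k_-i`; its multimer has mean
`b_i = (beta_i/beta_-i) a_i^{n_i}/n_i!`. With diffusion, the monomer means
instead solve the linear transport balance
`(diag(k_-) + Omega-Laplacian) a = k(d)`; the conditional network is weakly
reversible with deficiency zero, so the product-Poisson form persists with
the deterministic complex-balanced equilibrium as its mean vector. The
`n_i!` in the multimer mean comes from the stochastic mass-action
propensity `beta * choose(x, n)`, whose deterministic limit is
`(beta/n!) x^n`; the package uses that propensity convention consistently
in the simulator and the ODE backend, so all three views of the model agree.

As `epsilon -> 0` the promoter process becomes an autonomous finite Markov
chain on the `L` configurations. Averaging each binding propensity against
the current conditional law turns `TF + D_j -> D_j'` into a finite-chain
transition at rate `alpha * E[TF | D = d]`; unbinding keeps `alpha_-`. This
is `build_reduced_generator()`. The package also implements the defining
projection form — stack the extended conditional PMFs, apply `Lambda_hat`
on a truncated lattice, and sum per block (`reduced_generator_direct()`) —
purely as an independent cross-check; the test suite requires the two
constructions to agree to `1e-8` entrywise.

The stationary law `lambda` of the reduced chain then gives the SPK-limit
stationary PMF as the mixture `pi(x) = sum_d lambda_d pi_{X|d}(x)`
(`mixture_pmf()`). Each Poisson component is a *mode* in the sense used
throughout: a component of the mixture, located at its conditional mean
vector. Distinct nearby components can merge into a single local maximum of
the PMF, so `find_modes()` reports both views: distinct positive-weight
component locations, and strict local maxima found by exhaustive scan of
the truncation box.

### Reducible reduced chains

Non-leaky circuits (zero production in the unbound configuration) make the
reduced chain reducible: once the activator is gone, some configurations
can never be re-entered. The principal-eigenvector characterization of
`lambda` is then ambiguous, and the package resolves it by communicating
classes: with exactly one closed class its stationary law (zeros elsewhere)
*is* the unique stationary distribution — this covers the non-leaky
self-activating gene, the toggle switch's weightless all-bound state, and
the repressilator's two weightless states. With several closed classes the
chain has no unique stationary law; `stationary_weights()` then requires an
initial promoter distribution and weights each class by its absorption
probability, reporting non-uniqueness in an attribute rather than silently
picking a kernel vector.

## Tunable parameters that matter

* `epsilon` (dimensionless): gene/protein time-scale ratio. The reduction
  is exact in the limit; at finite `epsilon` the predictions emerge once
  the largest rate of `epsilon * Lambda_r` is below about half the protein
  decay rate (the two-to-one rule, tested against FSP on the toggle).
* `alpha/alpha_-` (dissociation ratio, per TF copy): scales how strongly a
  mode's weight responds to its TF's conditional abundance.
* `k_j/k_-` (copies): the component locations themselves. Only these move
  the modes.
* `beta/beta_-` and `n`: the multimerization ratio and cooperativity index
  enter the weights through `E[TF|d]` but never the (monomer) component
  locations — cooperativity tunes how probable a mode is without moving
  it. The test suite asserts bit-identical locations across a `beta/beta_-`
  sweep on the toggle.
* `Omega` (per copy): diffusion coupling. For `N` identical coupled toggle
  switches the aggregated synchronized-limit modes sit at
  `i * k0/(N k_-)`, `i = 0..N`, per axis; `synchronized_limit()` reports
  the threshold `(k0 - k_-)/N` for synchronization-within-one-copy but
  never applies it, since the bound's exact form is a modeling choice.

## Numerical choices

* **Truncation**: evaluation boxes default to
  `mean + 10 sqrt(mean) + 20` per species — beyond any plotting need, with
  the leaked tail mass reported by the FSP solver. The CME assembly warns
  when a conditional mean exceeds half its bound.
* **FSP stationary solve**: reflecting closure (boundary outflow discarded,
  columns re-closed), then a sparsity-preserving solve that pins one
  well-supported state and solves the remaining nonsingular system before
  normalizing. Residuals are checked to `1e-10`.
* **Null spaces**: dense LU with a normalization row for the reduced chain
  (`L <= 4096` in practice), SVD fallback if the pivot degenerates.
* **Ties and merges**: coincident component locations are merged (weights
  summed) before counting; the component weight floor defaults to `1e-6`,
  separating structurally weightless configurations from numerical dust. A
  lattice point is a local maximum when it is `>=` all axis neighbors and
  `>` at least one.
* **ODE steady states**: `rhs = rate * prod(z^r/r!)` mass action in reduced
  coordinates (one promoter fraction per gene eliminated, removing the
  conservation null directions), `lsoda` integration to near-steady state
  from 200 log-uniform/simplex-uniform starts by default, damped-Newton
  polish with finite-difference Jacobians, equilibria deduplicated at an
  absolute tolerance scaled to the largest production ratio, stability from
  reduced-Jacobian eigenvalues (threshold `-1e-9`).
* **Oscillation detection**: a dominance episode is a run of at least 5
  samples (sampling interval `1/k_-`) with the same argmax protein; a
  switch is a transition between consecutive distinct episodes; the cyclic
  fraction is the share of switches following the ring order. The 5-sample
  run and the 0.8 cyclic-fraction threshold are exposed arguments — the
  underlying claim is qualitative and these make it checkable.

## What the fixtures emulate — and what they do not

The fixture catalog (`build_fixture()`) covers the canonical circuits:
bursting gene, self-regulating gene (leaky/non-leaky, cooperative or not),
toggle switch, populations of diffusion-coupled toggles, repressilator, and
two trans-differentiation (cell-fate) circuits. Fixtures whose defaults
follow published parameter sets are flagged `provenance: "paper"`; those
without a full published rate set (the coupled population and both
cell-fate circuits) are `provenance: "reconstructed"` — their parameters
were chosen once to satisfy every documented qualitative property of the
circuit (mode counts, production-rate rankings, synchronized mode locations
at 50/100/150) and are not tuned further.

One wiring choice deserves a note: in a repression ring, protein dominance
cycles *against* the repression arrows — from an X-dominant promoter state
the only feasible escape hands dominance to the gene whose repressor has
just vanished. The repressilator fixture is therefore wired so that the
observable claims (dominance order X→Y→Z and the small-time transition
preference in `Q(t) = expm(t Lambda_r)`) hold as stated.

These are single-copy, lumped-production models with a global time-scale
split. Passing tests show that the reduction, solvers and simulator are
mutually consistent and reproduce the analytic structure of these models;
they do not show that any real promoter is slow, that mRNA dynamics are
negligible in a given system, or that real cell-fate circuits have the
production ranks assumed here.

## Problem sizes used in the shipped checks

The finite-`epsilon` cross-validations run on 2-species truncated lattices
(up to about 60,000 CME states for the toggle) and a 3-species scaled
repressilator (box 20 per species). The cooperative two-gene circuits have
four protein species; their joint truncated CME is beyond desk scale at any
honest truncation, so the finite-`epsilon` validation covers each
*mechanism* on a smaller circuit instead (cooperative multimers on the
self-regulating gene; restricted configuration sets on a scaled
PU.1/GATA.1; a three-gene ring on the scaled repressilator). Simulated
occupancy comparisons use single runs of 5–7 million reaction events.

## Known limitations

* Only the zeroth-order term of the stationary PMF in `epsilon` is
  computed; no first-order correction is attempted.
* Up to two binding sites per promoter, single gene copies, homomeric TFs
  with one cooperativity index, one-step multimerization.
* The diffusion extension requires the conditional network to remain
  weakly reversible with deficiency zero (linear transport on monomers);
  anything else is rejected, not approximated.
* The FSP backend targets stationary laws; transient CME solutions are out
  of scope (sample paths come from the exact simulator instead).
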