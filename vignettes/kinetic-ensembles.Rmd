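---
title: "Kinetic-parameter ensembles for metabolic phenotypes: models, criteria and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic-parameter ensembles: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it
implements: the model and its assumptions, the tunable parameters and
their defaults, what the synthetic fixtures do and do not emulate,
the numerical choices, and the places where the design was genuinely
open and a decision had to be made.

## The model

A metabolic network is an ordered species table plus an ordered
reaction table.  Before any kinetics, every reversible reaction is
split into an irreversible forward copy (same id) and a backward copy
suffixed `_reverse` with reactants and products swapped.  Two matrices
summarize the split model: the signed stoichiometric matrix `S`
(species by reactions; products positive, reactants negative) and the
kinetic-order matrix `A`, which keeps only the reactant-side
coefficients.  Mass-action kinetics then assign each reaction the rate

$$v_i = k_i \prod_w [\chi_w]^{A_{wi}},$$

so a reaction with an empty reactant side (a supply/exchange) runs at
rate $k_i$, and the system evolves as $\dot x = S\,v(x)$ with clamped
species (nutrients, ions, exchanged metabolites) held constant.
Non-integer stoichiometric coefficients, as in biomass
pseudo-reactions, are accepted and used literally as kinetic orders:
the rate law above does not require integrality, and inventing a
rounding rule would silently change the kinetics.

Rate constants are the unknowns.  Rather than estimating a single
vector, the framework draws many vectors i.i.d. uniform on
$[\mathrm{low}, \mathrm{high})$ — default $[0, 100)$ — and lets the
downstream filters decide which vectors are compatible with each
phenotype.  Forward and backward constants of a formerly reversible
pair are sampled independently: the split model simply has two
directional reactions, and coupling them thermodynamically would
impose information the sampling deliberately avoids.

## Steady-state criterion

A simulation over $[0, t_e]$ (default $t_e = 100$ s, long enough for
central metabolism to relax after a nutrient pulse) is accepted as
steady when

$$\frac{\sum_w \sigma\!\left([\chi_w](\bar t, t_e)\right)}{M - S} < \theta,
\qquad \bar t = 0.9\,t_e,$$

with $\sigma$ the standard deviation of a species' concentration over
the final 10 % of the horizon, $M$ the number of species in the sum
and $S$ the number of excluded species.  Excluded species — clamped
ones, and species flagged non-internal such as accumulating products
(biomass, exported fermentation products) — contribute exactly zero to
the numerator and are counted in $S$.  The default tolerance is
$\theta = 0.001$ (0.1 %).

Two readings of this criterion were possible and both are provided.
The default treats $\sigma$ as an absolute standard deviation in
concentration units, because the criterion as written contains no
normalization.  An optional relative mode (`relative = TRUE`) divides
each $\sigma$ by the window mean, skipping near-zero means; this
matches the alternative reading "not varying more than 1 %" and is
useful when concentrations span orders of magnitude.  Similarly, the
denominator's $M$ is read as the number of species (the sum runs over
species), not the number of rate constants; the two coincide only by
accident of model size.  The denominator choice merely rescales
$\theta$, so users preferring internal-species-only denominators can
adjust $\theta$ accordingly.

Both solver failures and runs that end above $\theta$ are recorded as
*discarded* samplings — they are kept in the record table with
`passed = FALSE` and `NA` fluxes, never dropped silently, because the
discard fraction is itself a result.

## Fluxes and phenotype filters

For accepted runs, fluxes are evaluated by the mass-action law at the
final state $x(t_e)$, not averaged over the window: the criterion has
already certified that the window variation is below $\theta$, and a
single-state evaluation keeps the flux law exact.  Values below
$\varepsilon = 10^{-10}$ are set to exactly zero (strictly below:
$v = \varepsilon$ survives).  Thresholding happens *before* filter
evaluation, because the filters' predicates `> 0` and `= 0` are only
meaningful once numerical dust has been removed.

A phenotype filter is a conjunction of flux-sign predicates.  The five
built-ins encode aerobic growth on glucose, anaerobic growth on
glucose, and aerobic growth on acetate, succinate and glycerol; every
filter constrains the oxygen uptake, and only the anaerobic phenotype
uses an equality-with-zero predicate.  A record may satisfy zero, one
or several filters — overlap is information, not an error, and the
cardinality analysis reports the count of every exact phenotype
combination plus per-phenotype marginals.

Because the underlying dataset is "parametrizations × conditions",
there are two defensible units for intersection counts: the single
simulation record, and the parametrization with its per-condition
records collapsed by union.  Both views are computed
(`cardinality_analysis(by = "record")` / `by = "parametrization"`) and
labelled, rather than guessing which one a given figure used.

Filters derive from per-condition flux balance analysis: maximize the
biomass reaction subject to $S_{\mathrm{int}} v = 0$ and
$0 \le v \le ub$, with exactly one carbon uptake opened per condition
(bound 10, conventionally mmol gDW⁻¹ h⁻¹) and the oxygen uptake closed
in the anaerobic condition.  `derive_filter_targets()` classifies
reactions as class A (non-zero, after thresholding, in exactly one
condition) or class B (condition-defining uptakes and oxygenation).
FBA vertices can be degenerate; the classification is computed from the
returned vertex and should be read with that caveat — reactions whose
single-condition status depends on the chosen optimum are a known
limitation.

The linear programs are solved by an in-package two-phase dense simplex
with Bland's anti-cycling rule.  Flux-balance LPs are heavily
degenerate (every equality right-hand side is zero), which is exactly
the regime where naive pivoting cycles or crashes; Bland's rule is slow
in theory but robust, and the models this package targets (tens to a
few hundred reactions) are far below the sizes where a dense tableau
hurts.  The solver is unit-tested against exhaustive vertex enumeration
on toy networks.

## Ensemble characterization

Populated ensembles are summarized per reaction by the median and
standard deviation of steady-state fluxes and, optionally, of the
member rate constants.  Two groupings are supported: by simulated
condition (`sC`; records grouped by the condition they ran under) and
by filter satisfaction (`fC`; records grouped by the phenotypes their
fluxes satisfy, regardless of condition).  Empty ensembles are flagged,
not errors.

The *relevant fluxes* screen runs a two-sample Kolmogorov–Smirnov test
for every reaction and every unordered pair of conditions and calls a
reaction relevant iff $p < \alpha$ (default 0.05) for **all** pairs.
Exact p-values are used when both samples hold at most 50 observations,
asymptotic ones above.  No multiple-testing correction is applied by
default — the all-pairs conjunction is already a strong family-wise
guard, and the plain-significance convention keeps results comparable —
but Benjamini–Hochberg is available behind `p_adjust = "BH"`.  A
condition pair with fewer than two samples is skipped and reported, and
disqualifies the reaction.  Ensembles overlap, so the per-condition
samples feeding the tests are not strictly independent; the report does
not attempt to model that dependence.

## Reproducibility

Each parametrization's sub-seed derives from the master seed and the
parametrization index through a counter-based integer mix (two Lehmer
rounds modulo $2^{31}-1$), so individual vectors can be regenerated in
isolation and the full pipeline — sampling, integration, thresholding,
storage export — is byte-deterministic for a fixed master seed.
Fixture generators use their own seed namespace so that test data can
never collide with the sampling stream.  Results persist in an HDF5
store under `/parametrizations`, `/conditions/<id>/runs/p<id>`,
`/membership` and `/analysis`, with a layout-version attribute checked
on open; by default only final states are kept, since the criterion
needs only the final window and full trajectories at ensemble scale are
tens of gigabytes.

## Numerical choices

* Output grid: 1001 evenly spaced points on $[0, t_e]$, so the 10 %
  window holds 101 points (the criterion requires at least 3).
* LSODA tolerances: `rtol = 1e-6`, `atol = 1e-9`.  Trajectory values
  are clipped at zero on output and clamped rows are restored
  bit-exactly.
* Rates of reactions with more than 10 reactant species (biomass-style
  pseudo-reactions) are evaluated in log space to avoid premature
  under/overflow of the product.
* The zero-flux threshold ($10^{-10}$) is strict-less-than, matching
  the wording it implements.

## What the fixtures emulate — and what they do not

`make_linear_chain()` builds clamped-source chains
$X_0 \to X_1 \to \dots \to$ sink whose steady state is known in closed
form (throughput $J = k_1 X_0$, $[X_i] = J / k_{i+1}$); a zero
downstream constant produces unbounded accumulation, the canonical
must-fail case for the steady-state criterion.
`make_marker_network()` is a 20-reaction network carrying the sixteen
filter-marker reactions, wired so each growth condition's FBA optimum
activates exactly its own markers (oxidative glucose yield 2 vs
fermentative yield 1 forces clean route choices).
`make_phenotype_fixture()` plants known memberships — including empty,
multi-phenotype and the structurally impossible anaerobic+aerobic
combinations, which it refuses to generate.  `make_ks_fixture()` plants
all-pairs-separated, partially separated and null reactions with unit
variance.

These fixtures exercise every code path with known answers, but they do
not reproduce the stiffness spectrum, the flux magnitude range, or the
correlation structure of a real core metabolic model; passing on them
shows the machinery is correct, not that any particular biological
conclusion transfers.  Conversely, the full *E. coli* core case study
needs the third-party model and concentration files, which are not
redistributed here; with those supplied
(`options(kinensemble.ecc2_model = ...)`), the acceptance tests run the
split/count check, the per-condition growth-rate reproduction, and
scaled-down (n = 500) discard-rate and ensemble-proportion runs.

Full-scale outputs — dozens of relevant fluxes among a hundred-plus
reactions, exact ensemble counts from $5 \times 10^4$ records — are
functions of that full dataset and are not reproducible at the problem
sizes this package's test suite uses (chains of 3–5 species, ensembles
of tens to hundreds of parametrizations, 20-seed KS fixtures at
n = 200).  Those sizes were chosen so that the whole suite and the
acceptance script run in well under a minute while still pinning every
stage against an independent oracle.

## Known limitations

* Uniform sampling on $[0, 100)$ is a modelling choice, not a prior
  over plausible enzyme kinetics; log-uniform sampling is a natural
  extension the configuration leaves room for.
* No thermodynamic coupling between split pairs; net fluxes of a
  formerly reversible reaction are reported as two non-negative
  directional fluxes.
* FBA alternate optima can blur the class-A classification (see
  above).
* The KS screen treats overlapping ensembles as independent samples.
* The store is single-writer; there is no concurrent access.
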