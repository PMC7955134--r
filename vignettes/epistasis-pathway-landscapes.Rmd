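---
title: "Quantifying epistasis and pathway accessibility from mutant deconvolutions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying epistasis and pathway accessibility from mutant deconvolutions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiland)
library(dplyr)
```

## The additive model and its deviation

A deconvolution measures every genotype `g ⊆ {1..n}` between a parent
(no mutations) and a full n-site variant on one or more traits. Writing
`f(g)` for a genotype's trait mean and `w(g) = f(g) − f(parent)` for its
effect, the additive (null) expectation for a split of a multi-mutant into
disjoint non-empty parts `A₁..A_k` is

$$E = f(\text{parent}) + \sum_i \big(f(A_i) - f(\text{parent})\big),$$

and the epistasis of the split is `ε = f(∪A_i) − E`, identically
`w(∪A_i) − Σ w(A_i)`. Two consequences the test suite exploits as
invariants: `ε` is symmetric in the parts, and nested splits decompose as
`ε(A,B,C) = ε(A, B∪C) + ε(B, C)`.

Everything operates on the trait's **own scale** (%, kJ/mol, min⁻¹). We
deliberately do not log-transform: the interaction magnitudes users compare
against published matrices are plain differences on each trait's scale. A
fitness-style multiplicative analysis can be emulated by deriving a
log-trait before analysis, but it is not the default.

The reference state is the experiment's parent (here F87A), not the wild
type: the shared background mutation is part of every genotype and cancels
from every `w`.

### Error propagation

With `k` parts, the parent mean enters `E` with coefficient `k − 1`, so
under independent measurement errors

$$\mathrm{sem}(E)^2 = \sum_i \mathrm{sem}(A_i)^2 + (k-1)^2\,
\mathrm{sem}(\text{parent})^2,\qquad
\mathrm{sem}(\varepsilon)^2 = \mathrm{sem}(\cup A_i)^2 + \mathrm{sem}(E)^2.$$

These first-order formulas are exact for linear combinations; the tests
confirm them against Monte-Carlo resampling (10⁵ normal perturbations of
the genotype means) to within 10%. SEMs of *derived* traits
(`derive_trait()`) are preferably recomputed per replicate — replicate *i*
of each input trait combined with replicate *i* of the others — falling
back to a numeric delta method on the means when raw replicates are
unavailable.

A caveat worth knowing: with `n = 2` replicates the sample-SD-based SEM is
itself noisy and biased low (the expectation of the sample SD at `n = 2`
is ≈ 0.80 σ), so significance thresholds inherit that bias. The SEM
calibration property in the tests therefore runs at `n = 4` replicates,
where the bias is small; at `n = 2` the same property would fail for the
estimator, not the propagation.

## The interaction taxonomy

`classify_epistasis()` maps each split to one of seven classes from the
signs of the (orientation-adjusted) part effects, the combined effect, and
`ε`:

| parts' signs | combined sign | label |
|---|---|---|
| any | — , \|ε\| ≤ tol | `ADD` |
| mixed | any | `+SE` / `−SE` by sign of ε |
| all same | same as parts | `+ME` / `−ME` by sign of ε |
| all same | opposite (beyond tol) | `+RSE` (parts deleterious) / `−RSE` (parts beneficial) |

"Beneficial" is read on the trait's declared orientation
(`higher_is_better` in the trait metadata), so a trait where smaller is
better is classified on the flipped scale. For k-way splits "both"
generalises to "all parts".

Numerical choices, all configurable:

* **ADD threshold** — `|ε| ≤ max(k_sig · sem(ε), abs_tol)` with defaults
  `k_sig = 1`, `abs_tol = 0`. A one-SEM band is the weakest defensible
  rule that still calls a −0.2 deviation with SEM 0.2 additive while
  keeping a 1.0 deviation with SEM 0.2 epistatic; `ε` is always reported
  regardless of the label, so stricter users can re-threshold.
* **Part-sign ties** — a part effect within `max(k_sig · sem(w), abs_tol)`
  of zero (the SEM of `w` includes the parent's) has no resolvable sign.
  It is grouped with the majority sign of the resolvable parts and the row
  is flagged `marginal`. Rationale: a sign-epistasis call that hinges on
  noise around zero is unstable; grouping yields the more conservative ME
  call while the flag preserves transparency. If *no* part is resolvable
  the shared sign falls back to the combined effect's (then ε's) sign.
* **Sign flips** — RSE requires the combined effect to exceed its own
  threshold; a "flip" within noise is ME.

One structural fact worth recording: a label pattern that demands sign
epistasis on all three single+single pairs of a 3-site system is
unsatisfiable — SE requires opposite part signs, and three mutually
opposite signs cannot exist. Published matrices sometimes show such
patterns because each row was thresholded on separately estimated errors;
a single-valued dataset can reproduce the interaction magnitudes and the
per-trait class *counts*, but not necessarily every row's label.

## Split enumeration

`enumerate_splits(n, mode)`:

* `standard` — every unordered pair of disjoint non-empty mutation sets
  (the binary split of every achievable sub-genotype) plus, for `n ≥ 3`,
  the all-singles split of the full genotype. For `n = 3` this is the
  canonical 7-row matrix (6 binary + 1 tertiary); for `n = 4`, 25 + 1.
* `binary_only` — the pairs only.
* `all_kway` — every set partition (≥ 2 blocks) of every sub-genotype.

Order is deterministic: union size, then union bitmask, then parts.
Splits whose part, union or parent genotypes are unmeasured for a trait
are skipped and listed with reasons, so partial deconvolutions analyse
cleanly.

## Pathway accessibility

`enumerate_pathways()` lists all `n!` stepwise orderings (numbered
lexicographically by site index — for three sites, pathways 5 and 6 are
the two introducing the third site first). A step `g → g+i` is permitted
on a trait when its oriented change satisfies `Δ ≥ −tol` with
`tol = max(k_sig·√(sem_from² + sem_to²), abs_tol)`; a pathway is
*favoured* iff every step is permitted on **every** considered trait.
Local minima are thus operationalised per step; ties (including exactly
flat steps) are permitted, because with duplicate-level noise an exact tie
carries no evidence of a valley. Verdicts are invariant under positive
affine rescaling of a trait (SEMs rescale with the values), and the
multi-trait favoured set is exactly the intersection of the single-trait
favoured sets — both are tested properties.

`landscape_grid()` exports the long-format (pathway, step, genotype,
trait, value, sem) table; `plot_landscape()` renders it as a
value-faithful heat map with no interpolated surface.

## The selectivity free-energy transform

A product fraction `p ∈ (0,1)` toward the target regioisomer maps to the
relative free energy of the competing transition states,
`ΔΔG‡ = RT·ln(p/(1−p))` (R = 8.314 J mol⁻¹ K⁻¹; default T = 298.15 K, the
assay temperature). The transform is antisymmetric and strictly monotone;
its delta-method SEM is `RT·sem(p)/(p(1−p))`. Values of exactly 0 or 1
are refused (the energy is undefined) unless an explicit `clamp` is
given. By default `p` is interpreted on the *total* basis — target
product over all quantified products — because selectivity tables
routinely include minor regioisomers; a pairwise basis is the same
transform applied to a two-product fraction.

## The synthetic generator and the reference dataset

`simulate_deconvolution()` draws complete `2^n` datasets from an explicit
additive-plus-interaction model
`f(g) = parent + Σ_{i∈g} aᵢ + Σ_{S⊆g, |S|≥2} ε_S`, with i.i.d. normal
replicate noise (optionally proportional to the mean) and a fixed seed.
Its defaults mirror the study design the package targets: 2 replicates
per genotype-trait and three-site deconvolutions. Because the analysis
inverts exactly this model, zero-noise datasets must be (and are) decoded
exactly: pairwise splits recover the injected `ε_S`, nested splits their
nested sums, and purely additive data classifies `ADD` everywhere. What
the generator does **not** emulate: correlated errors between traits
measured on the same enzyme preparation, day effects, heteroscedastic
HPLC quantification floors, or any mechanistic enzyme kinetics. Passing
tests on synthetic data therefore validate the *inference machinery*, not
the measurement model of any particular assay.

`bm3_fixture()` is a frozen synthetic stand-in for the P450 BM3
R47I/T49I/Y51I deconvolution, built by constraint solving rather than
simulation: anchored values (the published turnover-frequency series
11 → 21 → 72 → 158 along the Y51I-first route, the 37% coupling-efficiency
plateau of `-II` and `III`, selectivity free energies 0 for the parent and
5.6 kJ/mol for `III` with singles summing to −3.45 kJ/mol) are combined
with values solved from the published interaction magnitudes, and
remaining degrees of freedom are fixed once to documented, plausible
choices (tagged `assumed` in the provenance sidecar). Per-trait SEMs are
free choices set so the singles' expectation SEM is 0.25 kJ/mol and every
anchored class label is significant at `k_sig = 1`. Because the published
intermediates are rounded, derived quantities can differ from printed
ones by ~1 in the last digit (e.g. the three-way turnover-frequency
interaction computes to 141 against a printed 140, and 9.05 kJ/mol
renders as "9.1" at one decimal). The fixture's kinetic columns are each
internally consistent with their interaction identities but cannot
additionally satisfy `PFR = NCR × CE` across traits; the validator
reports this, by design.

## Problem sizes used in the checks

The bundled verification runs at the scale of the study design it mirrors:
`n = 3` sites (8 genotypes, 7 splits, 6 pathways) for all dataset-level
checks, `n = 4` for enumeration and decomposition properties, 1,000
random datasets for the decomposition identity, 10⁵ draws for
Monte-Carlo SEM comparisons, and 500 seeded simulations for SEM
calibration. All are fast on a single CPU.

## Known limitations

* No multiple-testing correction across traits or splits: with 7 traits ×
  7 splits at `k_sig = 1`, some nominally significant interactions are
  expected by chance. Raise `k_sig` or post-filter on `epsilon_sem`.
* Not a regression/Walsh-basis framework: incomplete landscapes are
  handled by skipping unevaluable splits, not by fitting.
* No population-genetic pathway weighting (fixation probabilities,
  adaptive walks); "accessible" is a deterministic no-valley criterion.
* The two-replicate SEM caveat above applies to any real dataset of this
  shape.
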