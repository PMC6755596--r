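---
title: "Fuzzy molecular descriptors by Choquet-integral aggregation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy molecular descriptors by Choquet-integral aggregation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(choqmd)
```

## The model

Global molecular descriptors of the form "aggregate a vector of per-atom
contributions" implicitly assume the contributions are independent: a sum,
norm or moment is an additive functional of the LOVI vector.  `choqmd`
treats the LOVI vector instead as a set of *interrelated* criteria and
fuses it with the Choquet integral against a fuzzy (non-additive) measure.
Two ingredients parameterize the fusion:

1. **Singleton densities** `s(x_i)`, one per contribution, summing to 1.
   They are generated from the very vector being fused by the AO
   functions: AO1 assigns density proportional to `b_i^alpha`, AO2 to
   `(1 - b_i)^alpha` after min–max rescaling.  The exponent
   `alpha` in `[0, 1]` interpolates between the uniform measure
   (`alpha = 0`, with the convention `0^0 = 1`) and fully
   magnitude-driven weights.
2. **The L_mδ measure**, a closed-form capacity built on those densities.
   Its single parameter `L >= -1` tunes the interaction it encodes:
   subadditive (low synergy) for `-1 < L < 0`, additive at `L = 0`,
   superadditive (high synergy) for `L > 0`, and the P-measure (max) at
   `L = -1`.  Unlike the Sugeno λ-measure it needs no polynomial root.

The integral itself follows the convention of the descriptor literature
it extends: values are sorted *decreasingly* and each value multiplied by
the measure increment of the nested tails of smaller-or-equal elements,

$$C_\mu(x) = \sum_{i=1}^{N} x_{(i)}\,\bigl[\mu(T_i) - \mu(T_{i+1})\bigr],
\qquad T_i = \{x_{(i)}, \dots, x_{(N)}\},\ T_{N+1} = \emptyset .$$

This is the mirror of the ascending textbook form; the two coincide for
additive measures but differ for general capacities, so `choquet()`
exposes `standard = TRUE` for comparison while the descending form is the
default.  The printed index form of the defining sum in the source
literature is internally inconsistent with its own worked three-element
expansion; we follow the expansion, which is unambiguous and matches the
stated monotonicity of the measure sequence, and the test suite contains
an independently coded transcription of that expansion which must agree
with the production path to 1e-12.

## Boundary conditions and exactness of the stated properties

Two places where the closed form needs care, both verified numerically in
the test suite:

* **Upper boundary at `L = -1`.**  For sum-normalized densities the max
  branch alone would give `g(X) = max(s) < 1`.  The definition declares
  `g(X) = 1` explicitly, so `lmdelta_measure()` applies the branch
  formulas to proper nonempty subsets and returns the definitional
  boundaries otherwise.  The plain `p_measure()` stays the literal max,
  and coincides with `L = -1` on proper subsets.
* **Sign of the interaction.**  Sub-/superadditivity by the sign of `L`
  is *exact on disjoint singleton pairs* (for `L > 0` the added ratio
  term is strictly positive), and that is the domain on which the
  property suite asserts it.  For larger disjoint pairs the closed form
  admits small violations in either direction; two counterexamples,
  checked by hand against the formula: with `n = 5`,
  `s = (.143, .325, .127, .180, .224)`, `L = -0.25` the union of `{4}`
  and `{1,2,3}` measures 0.7445 > 0.7437 = the sum of the parts; with
  `n = 4`, `s = (.7579, .1042, .0082, .1296)`, `L = 1` the union of `{2}`
  and `{1,3}` measures 0.9910 < 1.0156.  Users relying on a strict
  synergy interpretation should read `L` as a tendency, not a guarantee.

## Descriptor families

The classical summation families extend to fuzzy form by replacing the
outer sum with the Choquet fusion of the same contribution multiset:

| family | multiset fused | classical instance |
|--------|----------------|--------------------|
| FMD1 | `alpha' L_i^lambda'` per atom | first Zagreb (`alpha' = 1, lambda' = 2` on degrees) |
| FMD4 | `alpha' (L_i L_j)^lambda'` per *ordered* adjacent pair | second Zagreb (1, 1), Randić (1, −1/2), Balaban-like (`B/(C+1)`, −1/2) |
| FMD5 | ditto over all ordered pairs `i != j` | distance-type sums |
| FMD6 | per-fragment Choquet of `L_i^lambda'`, summed over fragments | Kier–Hall order-m (−1/2 over m-edge paths) |
| FMD7 | FMD4 restricted to a fragment | autocorrelation |

Design points:

* **Ordered pairs.**  The printed double sums run over all `i, j`, so
  each undirected edge contributes twice.  The classic edge-based Randić
  index is therefore half the classic counterpart used here; the factor
  is documented rather than silently absorbed.
* **Structural zeros.**  Pairs with `a_ij = 0` are excluded from the
  FMD4/FMD7 multiset by default: including them as zeros would let
  molecule size distort the reordering step.  A literal reading is
  available via `include_zero_terms = TRUE`.
* **FMD6 fuses powers, not products.**  The fuzzy fragment family
  Choquet-fuses the `lambda'`-powered LOVIs of each fragment's vertices
  (densities recomputed and hence renormalized within the fragment, since
  the measure needs densities summing to 1 on its own criterion set).
  Under the uniform additive measure this reduces to the *mean* of the
  powered LOVIs per fragment — not to the classical product form
  `(prod L_i)^lambda'`, which is a genuinely different functional.  On
  the 3-carbon chain with `lambda' = -1/2` the uniform-additive fuzzy
  value is 1.7071 while the classical Kier–Hall 1-chi is 1.4142; the test
  suite carries both oracles and asserts each against its own definition.
* **Density provenance.**  Densities always come from the aggregated
  multiset itself (the belonging degree of a contribution is determined
  by its magnitude within the set), not from any external weighting.

## Geometric LOVI pipeline

`qubils_lovis()` implements the two-linear geometric pipeline: relation
matrix → Hadamard power `k` → stochastic normalization → per-atom split →
(bi)linear contraction with atomic property vectors (bundled Pauling
electronegativities and IUPAC atomic masses, user-extensible by CSV).
Choices that were genuinely open:

* **Matrix entries** are the metric values themselves (Euclidean
  distance in Å; Soergel coefficient after translating the coordinates
  per axis into the non-negative octant, since the coefficient needs
  non-negative components).  The metric slot is pluggable.
* **Negative powers** apply the reciprocal off-diagonal only, mapping
  zero entries and the diagonal to 0, so the full `k = ±1..±12` range is
  usable on hollow matrices.
* **Order of operations**: the power is applied to the non-stochastic
  matrix *before* normalization (the workflow lists both in one step, so
  an order had to be fixed); `power_after_norm = TRUE` gives the
  alternative.
* **Atom-level split** keeps row *a* and column *a*.  Summing the splits
  over all atoms counts each off-diagonal entry twice; the identity is
  documented so users needing a strict partition can halve.
* **Double-stochastic normalization** (Sinkhorn, residual `< 1e-8`, max
  1000 iterations) is provided for two-tuple matrices only, matching the
  notation of the source family; three-/four-tuple extensions (bond-angle
  and dihedral tensors, middle-index convention for the angle) ship as
  optional extras.

Hydrogens are kept by default (`include_h = TRUE`); the upstream
convention is unstated, so the flag is explicit.  No implicit hydrogens
are ever added and no geometry is optimized: structures are consumed with
the 3D coordinates they arrive with.

## QSAR validation statistics

* `q2_loo()` uses the exact PRESS/hat-matrix identity for OLS, which is
  algebraically identical to refitting each held-out case (the tests
  verify equality against explicit refits).
* `q2_boot()` is a reconstruction: mean out-of-bag predictive q² over
  seeded bootstrap resamples (`B = 1000` by default).  The exact protocol
  of the historical modelling software is undocumented, so this statistic
  is not expected to replicate published bootstrap values bit-for-bit.
* `ga_select()` encodes variable subsets as p-bit membership masks with
  tournament selection (size 3), uniform crossover, per-bit mutation
  `1/p` and elitism, fitness `q2_loo`, fixed subset size by repair.
  Population 50 and 100 generations are defaults only; the metaheuristic
  was named in the source methodology but none of its settings were, and
  all are exposed.
* `wilcoxon_exact()` enumerates all `2^m` sign assignments (as a
  convolution over doubled midranks — exact, and equivalent to the
  literal enumeration that serves as the test oracle).  With `n = 8`
  pairs the normal approximation would be inappropriate; the exact test
  reproduces `p = 2/2^8 = 0.0078125` when every difference has the same
  sign.
* `adjusted_skewness()` is the sample-adjusted Fisher–Pearson coefficient
  (the SPSS convention) — the only common convention consistent with the
  packaged paired table's published summary values (0.095 / 0.727), which
  the tests recompute from the raw column values.
* `friedman_ranks()`/`select_best()` implement the first-step-rank
  selection rule: configurations with average rank below
  `mean − SD` of the group's average ranks.

The packaged `qext_pairs()` table transcribes the eight published
(fuzzy, non-fuzzy) external-validation Q² pairs; it is an *input* to the
comparison statistics, not something this package claims to recompute —
regenerating the per-dataset models would require external structure
files, third-party geometry optimization and an unspecified GA protocol,
which is out of scope.

## Synthetic data and what the tests do (and do not) show

`fixture_molecules()` provides geometries with known structure (collinear
3-chain at 1.54 Å, tetrahedral 5-atom star at 1.09 Å, planar hexagon at
1.40 Å, configurable collinear alkane) and `random_molecule()` seeded
chain molecules in a 10 Å box.  These exercise every code path —
degenerate degrees, rings, branching, symmetry — and make hand oracles
feasible, but they are not conformationally realistic molecules: passing
tests demonstrate algebraic correctness of the descriptor machinery
(invariance under rigid motion and renumbering, normalization
invariants, reductions to classical indices), not chemical validity of
any particular descriptor choice on real structures.

Problem sizes used by the verification suites: the measure-axiom suite
enumerates all subsets for 200 random density vectors with `n = 2..6`
over the nine-point L grid; the Choquet suite checks 1000 random triples
against the independent expansion; the GA sanity check runs 100 seeded
planted-signal recoveries at `n = 60` cases × 22 variables with
population 30 and 15 generations.  These sizes give exhaustive coverage
of the subset lattice and tight Monte-Carlo bounds while keeping the
default test run fast.

## Numerical conventions

* Boundary/normalization tolerances: 1e-9; algebraic identities asserted
  at 1e-10 to 1e-12.
* Choquet ties are broken stably by original index (the result is
  tie-invariant; determinism just needs a rule).
* Negative aggregation inputs are rejected by default (the integral is
  defined on non-negative reals); `shift = TRUE` opts into subtracting
  the minimum, with a warning.
* Degenerate AO inputs (all equal, all zero) yield the uniform measure
  rather than an error, keeping single-atom and symmetric molecules
  computable.
* Sugeno λ roots are found by sign-bracketed bisection to 1e-12;
  sum-normalized densities short-circuit to λ = 0.

## Known limitations

Chirality codification, neighborhood-quotient cutoff matrices,
local-fragment matrices and the full metric catalogue of the geometric
descriptor family are not implemented.  SMILES input, aromaticity
perception and 3D embedding are out of scope — the package consumes V2000
SDF with coordinates as given.  The descriptor namespace of the
historical software is not replicated; configurations are addressed by
user-chosen labels.
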