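---
title: "Two-state hinge backbones and conformational-selection kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-state hinge backbones and conformational-selection kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hingekit)
```

`hingekit` implements two connected pieces of machinery for switchable
"hinge" proteins built on helical repeat scaffolds: the geometric
construction of a second designed conformation by a pivot-helix register
shift, and the three-state kinetic model that couples the hinge's
conformational pre-equilibrium to effector binding. This vignette explains
the models, the assumptions behind them, the tunable parameters, and the
numerical choices, in enough detail that a user can judge what the package's
tests do and do not demonstrate.

## The pivot-shift construction

A designed helical repeat protein (DHR) is an array of straight, antiparallel
alpha-helices with near-identical repeats. Its native backbone serves as the
hinge's effector-free conformation, **state X**. The second conformation is
generated, not designed from scratch: a copy of the whole protein is
superposed onto itself along one helix (the **pivot**) with its residue
window slid by an integer register shift *s*. Because an ideal helix is a
discrete screw, this alignment is itself a screw motion about the pivot axis
with rotation close to *s* × twist (about 100 deg per residue) and
translation close to *s* × rise (about 1.5 Å per residue). `hingekit`
computes the transform by least-squares superposition of the shifted CA
window (`pivot_shift_transform()`) and reports its Chasles decomposition
(`screw_decompose()`), so the realised rotation and slide can always be
inspected rather than assumed.

**State Y** combines helices 1..p of the original frame (domain 1) with
helices p+1..n of the transformed copy (domain 2); the loop between the
domains is severed and its required span is recorded rather than rebuilt.
The helix displaced by the motion — either the helix following the pivot, in
the original frame, or the transformed pivot helix of the copy — becomes the
**effector peptide**. By construction this yields two exact compatibility
invariants that the test suite asserts rather than assumes: domain 1 is
bitwise identical between the states, and the union of domain 1 with the
peptide (or of the peptide with domain 2) superposes with zero RMSD onto the
corresponding stretch of the parent (or of the transformed copy). These
invariants are what make a single amino-acid sequence compatible with both
conformations in the real design problem.

Loop closure is deliberately out of scope: `loop_feasibility()` only checks
the geometric bound `gap <= 3.8 * (n_loop + 1)` (one CA-CA virtual bond per
added residue), and the emitted state-Y model keeps the two domains as
separate chain segments. No loop atoms are fabricated.

## The two-state gate

The original selection logic requires (i) that the apo hinge prefers state X
and (ii) that the peptide-bound state Y complex is the global minimum.
`hingekit` reproduces this *logic* with a deliberately simple surrogate
score, `contact_energy()`:

```
E = -(number of inter-segment CB-CB pairs < 8 Å) + 25 * clash_count
```

computed over a per-helix rigid-segment partition, with the peptide as its
own segment. The gate (`two_state_gate()`) passes when `E(X) < E(Y hinge)`
and `E(complex) < E(X) + E(isolated peptide)`; an isolated helix has energy
zero by definition. This is a contact count, not a physical potential: it
orders alternative geometries of the same scaffold and reproduces the
selection behaviour (clashing or contact-poor shifts fail; groove-forming
shifts pass), but its magnitudes are not energies and are not comparable to
any force-field score. The clash penalty (25 per clash, clash = non-bonded
heavy-atom pair under 3.2 Å with sequence separation > 2) simply makes any
steric overlap dominate the contact term.

Label-site and staple-site selection operate on the same CB geometry. A
residue counts as surface-exposed when its CB has at most 14 CB neighbours
within 10 Å in both states — a burial proxy chosen because true
solvent-accessible surface area is out of scope; it errs on the permissive
side for an idealised scaffold with no side chains. Staple candidates pair
residues whose CB-CB distance falls in the disulfide window (3.5-5.5 Å) in
exactly one state and exceeds 10 Å in the other, so an oxidised bond locks
that state.

## The synthetic scaffold generator

`build_repeat_protein()` produces a deterministic stand-in for a DHR: ideal
straight helices (default 20 residues, rise 1.5 Å/res, twist 100 deg/res)
packed antiparallel on a triangular lattice with 10 Å between adjacent axes,
two helices per repeat, three-residue connecting loops, and an exact rigid
repeat operator between repeats. Helix atom positions come from cylindrical
constants frozen out of an internal-coordinate build with ideal helical
torsions; the carbonyl oxygen is tilted outward (keeping its 1.23 Å bond and
a 120.5 deg CA-C-O angle) so that an isolated helix contains no non-bonded
pair under the 3.2 Å clash cutoff — the generator guarantees a clash-free
parent at default parameters, and errors with the first offending pair
otherwise. Loops are circular-arc CA paths with placeholder N/C/O atoms.

What the fixture emulates: the repeat architecture, idealised helix
geometry, exact repeat symmetry, and enough spatial realism that helix
detection, axis fitting, screw recovery, gating, and site selection exercise
the same code paths as a real backbone. What it does not emulate: supercoil
curvature, sequence, side chains, loop torsion realism, or the energetic
frustration of real designs. Tests passing on the fixture therefore validate
the geometry and selection *machinery*, not the designability of any real
scaffold.

Default test problem sizes: 4 repeats (8 helices, 181 residues), pivot at
helix 4, register shifts in -6..+6. At these sizes the full
generate-gate-sites pipeline completes in a few seconds.

## The three-state kinetic model

The binding-competent conformation Y is rare in the apo ensemble and is
selected, not induced:

$$X \underset{k_{-1}}{\overset{k_1}{\rightleftharpoons}} Y
  \underset{k_{-2}}{\overset{k_2 [P]}{\rightleftharpoons}} YP$$

with mass-action dynamics integrated by `simulate_kinetics()`. Derived
quantities (`derive_equilibrium()`):

* conformational equilibrium constant `K_conf = k1 / k_m1`,
* apo state-Y fraction `F_Y = k1 / (k1 + k_m1) = K_conf / (1 + K_conf)`,
* intrinsic site affinity `K_D,intrinsic = k_m2 / k2`,
* apparent affinity `K_D,app = K_D,intrinsic / F_Y`.

When conformational exchange is much faster than binding
(`k1 + k_m1 >> k2 [P] + k_m2`), the X/Y manifold stays at equilibrium during
association and the observed pseudo-first-order rate is
`k_app = k2 F_Y [P] + k_m2`: the slope of `k_app` against concentration is
`k_on = k2 F_Y` (`pre_equilibrium_kon()`, which carries a validity flag at a
caller-supplied reference concentration; the threshold is a 10-fold
separation). Dissociation is identified with `k_m2` — release is not gated
by the conformational step in this model.

Comparing observed on-rates between variants with identical microscopic `k2`
then measures relative state-Y occupancies: `infer_fy_from_kon_ratio()`
implements `F_Y = F_Y,ref × k_on / k_on,ref`, the inference used to place a
disulfide-locked state-Y variant (taken as 100% Y) as the reference against
which the original hinge's `F_Y` is read off a 200-fold slower slope as
0.5%. The identical-`k2` assumption is surfaced in the result rather than
buried, because a staple that locks a slightly perturbed state Y can violate
it; the inference direction (ratio to occupancy) is exact arithmetic either
way.

Stability-tuning mutations and staples act on `K_conf` only:
`apply_stability_shift()` multiplies it by `exp(ddG/RT)` (R = 1.98720425e-3
kcal/mol/K, T default 298.15 K; positive ddG favours Y). Because rate data
constrain only the ratio, where the change lands is a convention: the
default scales `k_m1` (the variant speeds up by leaving X no faster), the
alternative scales `k1`; both are exposed and neither touches `k2`/`k_m2`
(non-interface substitutions). `lock_state()` zeroes the opposing flux
(`k1 = 0` for locked X, `k_m1 = 0` for locked Y), the limiting cases of an
oxidised staple. Note the fold change in `k_on` under a ddG shift equals the
`K_conf` fold change only while `F_Y` stays well below 1; the package
computes the exact value, and the tests check the 22-fold worked example in
a regime (`F_Y = 2e-4`) where saturation contributes less than 1%.

## Observables, noise, and fitting

* **FRET**: ensemble efficiency `E = 1/(1 + (r/r0)^6)` mixed over state
  populations; the bound complex reports the state-Y label distance. The
  default Förster radius is 51 Å — typical for long-range dye pairs and
  configurable, since no single value is canonical.
* **FP**: the signal is the bound fraction of the labeled peptide; in
  association mode the hinge is the excess species. This orientation matters:
  a locked-Y hinge is FRET-silent (it never leaves the Y-distance manifold),
  so locked-versus-original comparisons run through the FP observable.
* **DEER surrogate**: `deer_distribution()` builds Gaussian mixtures (default
  sigma 3 Å) centred on the CB-CB distances of a label-site pair, standing in
  for spin-label rotamer clouds. These surrogates are *not* comparable to
  rotamer-library simulations of real nitroxide labels; they exist so the
  mixture decomposition (`decompose_deer()`, non-negative least squares with
  weight renormalisation and a collinearity flag at cosine similarity 0.99)
  can be exercised and validated.
* **Noise**: additive i.i.d. Gaussian on the signal; every stochastic
  simulator requires an explicit seed and is bit-reproducible given one.

Fitting mirrors the standard analysis chain: per-trace single exponentials
(`fit_exponential()`, semilog initialisation refined by
Levenberg-Marquardt), then a weighted linear regression of `k_app` against
concentration (`fit_pseudo_first_order()`); traces are fitted independently,
with no global fit, matching how such data are usually reduced. Titrations
are fitted with the depletion-exact quadratic isotherm by default
(`fit_isotherm()`): probe concentrations in these systems (0.1-1 nM) sit
near the low-nanomolar affinities, where the hyperbolic approximation biases
Kd upward — the test suite quantifies this (>20% bias at probe = 10 Kd,
versus <1% for the quadratic). The hyperbolic model remains available for
the dilute regime.

## Numerical choices

* ODE integration: `deSolve::lsoda` with relative tolerance 1e-10 and
  per-species absolute tolerances of 1e-12 times each conserved total, so a
  trace-level probe in a large ligand excess is still resolved to full
  relative accuracy; lsoda switches itself to an implicit method in stiff
  regimes. Conservation is enforced post hoc by projection onto the
  invariant manifold (drift is at machine precision regardless).
* With peptide clamped, `linear_solution_excess_p()` solves the linear
  three-species system by eigendecomposition, falling back to a matrix
  exponential (flagged) near defective rate matrices; it is the analytic
  oracle against which the nonlinear integrator is tested to 1e-6.
* Binding quadratics use the cancellation-free root
  `2ab/(b + sqrt(b^2 - 4ab))`, stable when Kd is orders of magnitude below
  the totals.
* Isotherm Kd is optimised on the log scale (positivity plus conditioning
  across orders of magnitude), initialised from a 40-point log-spaced grid
  search; `nls.lm` is used directly because stoichiometric titrations make
  the Kd gradient nearly singular and the stricter `nls` model construction
  rejects them.
* Superposition is Kabsch (SVD with reflection guard); helix axes come from
  a total-least-squares fit of the CA second differences (which point
  radially inward on a regular helix) plus an algebraic circle fit in the
  normal plane; the axis residual (RMS cylinder deviation) flags non-helical
  segments at 1 Å without withholding the fit.
* Screw decomposition reports angles in [0, 180] deg with the axis oriented
  for non-negative slide; below 0.1 deg of rotation the axis is undefined
  and a degenerate flag is set with the slide equal to the translation norm.
* Ties in site ranking break toward smaller residue indices; staple ranking
  prefers bond lengths central in the 3.5-5.5 Å window.

## Design choices where the problem was open

* The register-shift range and pivot choice are exposed as free parameters
  rather than enumerated: nothing constrains them a priori, and on the
  synthetic scaffold the gate itself cleanly separates workable shifts from
  clashing ones.
* State X retains all parent loops verbatim; only the inter-domain loop is
  severed in state Y.
* The competitor hinge in `simulate_competition()` is injected
  pre-equilibrated between its X and Y states (a protein added from a stock
  solution is at its own conformational equilibrium before it sees peptide).
* Whether a locked-Y staple changes `k2` or `k_m2` cannot be resolved from
  on-rates alone; the model keeps both adjustable but the F_Y inference
  assumes shared `k2`, and flags itself accordingly.

## Known limitations

No side chains beyond ideal CB atoms; no sequence design, structure
prediction, or physical energies; no loop construction; no real DEER signal
processing (background correction, Tikhonov inversion); no photophysics in
the FRET model beyond the ideal transfer law; two hinge conformations only,
with no unfolded or intermediate states. The geometry operates on, and is
validated against, idealised scaffolds — applying the gate or site selection
to experimental PDB files works mechanically but inherits all the caveats of
the contact-count surrogate.
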