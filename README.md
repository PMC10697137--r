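# hingekit

Tools for two-state "hinge" proteins: generating a second, fully structured
backbone conformation from a helical repeat scaffold, and modelling how the
conformational equilibrium of such a hinge couples to effector-peptide
binding.

`hingekit` is aimed at protein designers and biophysicists who work with
switchable de novo proteins. It covers the two computational halves of that
problem:

1. **Backbone geometry.** Starting from a designed helical repeat protein
   (DHR) — the hinge's effector-free conformation, *state X* — a copy of the
   protein is re-aligned along a chosen *pivot helix* with a residue register
   shift of *s*. On a regular helix this induces a screw motion of roughly
   *s* × 100° rotation and *s* × 1.5 Å translation about the pivot axis.
   Combining helices 1..p of the original (domain 1) with helices p+1..n of
   the shifted copy (domain 2) yields *state Y*; the helix displaced by the
   motion is extracted as the *effector peptide* that can bind the groove
   present only in state Y. Candidate designs are gated by a two-state
   contact-energy criterion (state X must be favoured for the apo hinge, the
   state-Y complex must be favoured once the peptide is present), and the
   package selects spectroscopic label-site pairs and state-selective
   disulfide staple sites from the CB geometry of the two states.

2. **Conformational-selection kinetics.** The hinge-peptide system is a
   three-state model,

   ```
          k1         k2 [P]
     X  <====>  Y  <========>  YP
          k-1        k-2
   ```

   with fast conformational pre-equilibrium. The fraction of binding-competent
   hinge is F_Y = k1 / (k1 + k-1), the observed association rate is
   k_on = k2 · F_Y, and the apparent affinity is
   K_D,app = K_D,intrinsic / F_Y with K_D,intrinsic = k-2 / k2.
   The package simulates FRET/FP association traces, equilibrium titrations,
   competition (chase) experiments and DEER-style distance distributions from
   these rate constants, and provides the inverse route: single-exponential
   fits, pseudo-first-order slope regression, tight-binding (quadratic)
   isotherm fits, non-negative mixture decomposition of distance
   distributions, and inference of F_Y from on-rate ratios between variants
   (for example a disulfide-locked state-Y hinge versus the original).

A deterministic generator of ideal helical-repeat backbones is included, so
the entire pipeline runs and is tested without any external structure files.

## Worked example

```r
library(hingekit)

# a synthetic 8-helix repeat protein (two-helix repeats, ideal geometry)
parent <- build_repeat_protein(repeat_spec(n_repeats = 4))

# hinge generation: pivot on helix 4, register shift of -1
states <- assemble_states(parent, hinge_spec(pivot_index = 4, shift_s = -1))
states
#> hinge_states: pivot helix 4 shift -1 ( following_original )
#>   screw: 100.0 deg / 1.50 A  loop gap: 8.3 A
#>   gate: PASS (E_x -352, E_y -331, E_complex -376)

# label sites whose separation shrinks upon switching to state Y
site_pairs(states, "decrease", top_k = 3)
#>     res_i res_j      d_x      d_y     delta
#> 570    35   177 32.80238 18.09849 -14.70389
#> 471    24   166 32.57189 18.02657 -14.54532
#> 447    24   163 35.12049 20.74948 -14.37101
```

The screw decomposition confirms the register shift acts as designed (one
residue of shift = 100° rotation + 1.5 Å translation along the pivot); the
gate report says state X is the low-energy apo state (E_x < E_y) while the
peptide-bound state Y complex is lower still (E_complex < E_x), and the best
label-site pair moves by ~15 Å between the states.

On the kinetics side:

```r
rates <- rate_constants(k1 = 10, k_m1 = 1990, k2 = 1e6, k_m2 = 0.01)
rates
#> rate_constants: k1 10, k-1 1.99e+03 s-1; k2 1e+06 M-1s-1, k-2 0.01 s-1
#>   F_Y 0.005, K_D,int 1e-08 M, K_D,app 2e-06 M

# a variant whose observed on-rate is 200-fold below a locked-Y reference
infer_fy_from_kon_ratio(5e3, 1e6, f_y_reference = 1)$f_y
#> 0.005
```

A hinge occupying state Y only 0.5% of the time binds its effector with an
apparent K_D diluted 200-fold relative to the intrinsic site affinity — the
quantitative signature of conformational selection that the package's
simulators and fitters reproduce end to end.

## Command line

A thin wrapper over the same functions is installed with the package:

```sh
HK=$(Rscript -e 'cat(system.file("cli", "hingekit", package = "hingekit"))')
$HK fixtures --repeats 4 --out parent.pdb --meta parent_meta.json
$HK generate --pdb parent.pdb --pivot 4 --shift -1 --out-prefix design
$HK sites --pdb parent.pdb --pivot 4 --shift -1 --mode decrease --out sites.csv
```

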