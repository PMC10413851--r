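---
title: "Composite-method post-processing for tautomer spectroscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite-method post-processing for tautomer spectroscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tautospec)
```

## The problem

Tautomers of nucleobases differ by the position of one or two labile
protons; in the gas phase several forms of cytosine coexist within a few
hundred cm⁻¹ of each other. Deciding which species a microwave or
matrix-isolation IR experiment is seeing requires electronic energies good
to roughly 10 cm⁻¹, equilibrium rotational constants good to about 0.1 %,
and anharmonic vibrational fundamentals good to a few cm⁻¹ — none of
which a single affordable electronic-structure calculation delivers.

The established answer is a *composite* strategy: several cheaper
calculations, each capturing one physical effect well, are combined
additively. The expensive electronic-structure computations themselves are
outside this package's scope; what `tautospec` implements is everything
*after* them — the combination layer and the spectroscopic and
thermochemical post-processing — so that every downstream number is
reproducible from tabulated per-level inputs:

* **Energies.** An explicitly correlated frozen-core coupled-cluster
  energy in a triple-zeta F12 basis is the base term. The residual
  basis-set error is estimated at the MP2-F12 level by the two-point
  inverse-cube extrapolation over triple/quadruple-zeta cardinals
  (`cbs_two_point()`, `cbs_correction()`), and core-valence correlation is
  added as the all-electron minus frozen-core MP2-F12 difference in a
  core-valence basis (`cv_correction()`). `composite_total()` stores the
  breakdown; the invariant `total = base + dCBS + dCV` is exact in double
  precision.
* **Geometries.** The same additivity applied per geometrical parameter:
  `geometry_scheme()` shifts each bond, angle and dihedral of a base-level
  structure by the core-valence change between two further optimizations
  (`r_base + (r_ae - r_fc)`). A "gradient scheme" — performing the same
  composition on analytic gradients inside the optimizer — gives closely
  agreeing structures but requires modifying electronic-structure codes,
  so it is documented here as a contract only and not implemented.
* **Rotational constants.** Rigid-rotor constants from the inertia tensor
  (`rotational_constants()`), ground-state constants via computed
  vibrational corrections, and semi-experimental (SE) equilibrium
  constants via the reverse correction of experimental ground-state
  constants (`apply_vibrational_correction()`, `semi_experimental()`).
* **Thermochemistry.** Harmonic ZPE, RRHO partition-function
  contributions, Boltzmann ratios and mole fractions
  (`rrho_thermo()`, `boltzmann_populations()`).
* **IR spectra.** Hybrid anharmonic fundamentals: high-level harmonic
  frequencies plus low-level anharmonic shifts, with a harmonic fallback
  for large-amplitude modes (`hybrid_frequency()`, `build_spectrum()`).

The package bundles transcriptions of the published reference tables for
cytosine (five low-lying tautomers/rotamers KA, EA, EAc, KI, KIc, plus
three high-lying forms), and `reproduce_reference()` regenerates every
composite-layer number from them in one call.

## Conventions and key parameters

**Units.** The internal working unit for energies is cm⁻¹, because
relative tautomer energies, ZPEs and vibrational frequencies are all
naturally quoted in it; hartree and kJ/mol are accepted on input
(`convert_energy()`). Rotational constants are MHz, moments of inertia
amu Å², bond lengths Å, angles degrees.

**Constants registries.** All conversion factors live in
`spectro_constants()` and are fixed when the registry is built, never
re-read per call. The default `"codata"` registry derives every factor
from CODATA-2018 `h`, `c`, `N_A`, `k`, and the atomic mass constant. A
second `"printed"` registry replaces the kJ/mol factor by the rounded
83.59 cm⁻¹/kJ·mol⁻¹ used in printed tables, for digit-exact table work.
The Boltzmann constant is pinned at 0.695034800 cm⁻¹/K (the CODATA value
to those digits); the inertia-to-MHz constant `h/(8π²)` evaluates to
505379.0084 MHz·amu·Å².

**Masses.** Principal isotopes (¹H, ¹²C, ¹⁴N, ¹⁶O) by default — the
main-isotopologue convention of rotational spectroscopy, and the natural
reading of published equilibrium constants, which never state their mass
convention explicitly. Lookups of unknown elements fail loudly rather
than defaulting.

**Sign convention for vibrational corrections.** The sources tabulate
ΔB\^vib without defining its sign. Cross-checking the published tables
fixes it: the composite equilibrium constant of the keto-amino form
(3904.3 MHz, a-axis) minus its tabulated correction (29.1 MHz) equals the
tabulated ground-state constant (3875.2 MHz) for all 15 species/axis
pairs. The package therefore adopts ΔB\^vib = B\^eq − B⁰ throughout, so
`B0 = Beq - dBvib` and `Bse = B0_exp + dBvib`; the two maps are exact
mutual inverses, which the test suite asserts.

**Rounding.** Printed tables round half away from zero; R's `round()`
rounds half to even. `round_half_away()` is used for every printed-digit
comparison. With it, the semi-experimental keto-imino row lands exactly
on the printed 0.1 MHz digits.

**Hybrid-IR fallback policy.** The anharmonic shift is trusted when the
low-level anharmonic fundamental is positive and the shift magnitude is
at most 300 cm⁻¹ (caller-overridable). Both amino tautomers have an
NH₂-inversion mode (mode 31) whose low-level VPT2 fundamental is negative
(−216 and −710 cm⁻¹): second-order perturbation theory cannot describe
this large-amplitude double-well motion, and the published hybrid columns
fall back to the bare high-level harmonic there (348 and 266 cm⁻¹). The
implemented rule reproduces both rows; whether the original tables were
produced by exactly this rule is not stated, so the policy is flagged as
inferred. The same inversion mode is harmonically acceptable for
*thermochemistry* (its frequency, 250–350 cm⁻¹, is high enough), so RRHO
sums use all modes as-is, with no free-rotor interpolation.

**Band assignment.** `assign_bands()` matches computed modes to observed
bands greedily, strongest computed intensity first, nearest band within a
window (default 30 cm⁻¹), one-to-one. This mirrors manual spectroscopic
practice and is deterministic; a globally optimal assignment could be
substituted without changing any interface.

**Symmetry numbers** default to 1 (all cytosine tautomers are C₁ or Cs);
the RRHO standard state is 1 atm, matching the toolchain behind the
published free energies; "room temperature" defaults to 298.15 K where
needed and is caller-overridable, since the sources never state it.

## Worked example

Composite assembly and populations at the matrix-deposition temperature:

```{r}
rel <- composite_relative_energies()
round(rel, 1)
pops <- boltzmann_populations(rel[c("EA", "EAc", "KA", "KI")], 450, "EA")
round(pops$ratio, 2)
```

The electronic-energy ratios 1.00 / 0.45 / 0.40 / 0.18 match the
published values; with free energies instead of electronic energies the
keto-amino form overtakes the enol rotamer (its relative ZPE is
−45 cm⁻¹), and the combined enol-amino mole fraction at 450 K is 0.66,
against 0.70 estimated from matrix-isolation band ratios.

Rotational bookkeeping:

```{r}
b0 <- computed_ground_state_constants()
round(b0$KA$B, 1)       # ground-state constants, composite geometry
se <- semi_experimental_constants()
round_half_away(se$KI$B, 1)  # semi-experimental reference constants
```

Hybrid IR, with the fallback row visible:

```{r}
ea <- reference_spectrum("EA")
ea[c(1, 31), c("mode", "label", "omega_high", "anh_shift", "hybrid", "fallback")]
```

## What the synthetic generators emulate

* `synthetic_rigid_rotor()` builds point-mass geometries with exact
  prescribed principal moments (closed-form axis masses, then a seeded
  random rigid motion). It exercises the full inertia pipeline —
  Euclidean invariance, the planarity identity I_c = I_a + I_b, the
  closed diatomic form — without any electronic-structure input.
* `synthetic_cbs_series()` produces energy series following
  E(k) = E_CBS + A·k⁻ᵖ exactly. With p = 3 the two-point extrapolation
  must recover E_CBS to machine precision; with p = 4 it leaves a
  residual of analytically predictable sign, a useful negative control.
* `synthetic_mode_set()` generates mode tables with controllable
  large-amplitude failures for the fallback logic.

These generators are idealizations: real basis-set convergence is only
asymptotically inverse-cube, real molecules are not point-mass rotors,
and real anharmonic shifts correlate across modes. Passing the property
suites therefore validates the *arithmetic and bookkeeping* of the
composite layer, not the physics of the underlying electronic-structure
methods — the latter is exactly what the bundled experiment-facing tables
probe.

## Numerical choices and degenerate inputs

* Two-point extrapolation requires distinct cardinals; equal inputs
  return the common value (a converged series is its own limit).
* Internal-coordinate extraction rejects angles within 1e-8 degrees of 0
  or 180 (undefined planes), naming the offending parameter; Cartesian
  rebuilding requires Z-matrix ordering and rejects near-linear reference
  frames. Dihedral differences are taken on the circle (shortest signed
  arc, wrapped to (−180°, 180°]), so combinations near ±180° cannot jump
  by a turn. The signed dihedral convention matches the major
  molecular-mechanics libraries (verified against an independent
  projection formula in the tests); round trips reproduce internals to
  1e-8.
* Principal-axis orientation for degenerate moments is made deterministic
  by forcing each eigenvector's largest-magnitude component positive;
  constants are reported sorted B_a ≥ B_b ≥ B_c regardless.
* Linear geometries have one vanishing moment; the corresponding constant
  is reported absent (`NA`) rather than infinite, and only when the
  caller declares the molecule linear.
* Fixture CSVs normalize typographic minus signs (U+2212) on ingest and
  store the printed rounded values — never back-inferred precision — so
  cross-table consistency checks use half-a-printed-digit tolerances
  (0.05 cm⁻¹, 0.1 MHz).

## Known limitations and source-table discrepancies

* Five of the 99 printed hybrid-IR rows are internally inconsistent in
  the source (the hybrid column differs by 1–10 cm⁻¹ from the value its
  own three component columns imply, a rule the other 94 rows satisfy
  exactly). `hybrid_table_discrepancies()` enumerates them; tests assert
  digit-exact reproduction on the consistent rows and that the
  disagreement set is exactly the enumerated one.
* The printed semi-experimental constants of the cis-enol rotamer (EAc)
  differ by up to 6.7 MHz from the stated definition (experimental
  ground-state constants plus low-level corrections); the other four
  species agree to the printed digit (one cell rounds 0.05 MHz the other
  way). The package computes from the definition and documents rather
  than reproduces that row.
* In the uracil error-statistics block, two method columns print a mean
  relative error larger than the maximum — impossible under the
  definitions that reproduce the composite column exactly; the rows
  appear transposed, and the implemented definitions are the validated
  ones.
* Published free-energy populations at 450 K (1.00/0.45/0.60/0.16) are
  consumed as inputs where needed: the harmonic frequency sets of two of
  the five species are not published, so this column is not recomputable
  from available data, and neither is the room-temperature ΔG column.
* No anharmonic partition functions, hindered-rotor corrections,
  Fermi-resonance deperturbation, centrifugal distortion, or solvation —
  all outside the composite layer this package implements.
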