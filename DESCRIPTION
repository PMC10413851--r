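Package: tautospec
Title: Composite-Method Post-Processing for Tautomer Spectroscopy and
    Thermochemistry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assembling and auditing composite quantum-chemistry
    results for tautomeric equilibria of biomolecule building blocks.
    Implements the additive composite energy layer (explicitly correlated
    coupled-cluster base energy, two-point n^-3 complete-basis-set
    extrapolation at the MP2-F12 level, and core-valence correction from
    all-electron minus frozen-core differences), the per-parameter geometry
    combination scheme, rigid-rotor rotational constants from Cartesian
    geometries, ground-state and semi-experimental rotational-constant
    bookkeeping with error statistics, rigid-rotor harmonic-oscillator
    thermochemistry and Boltzmann tautomer populations, and hybrid
    anharmonic IR spectra built from high-level harmonic frequencies plus
    low-level anharmonic shifts with a large-amplitude-mode fallback.
    Ships transcriptions of published reference tables for gas-phase
    cytosine tautomers together with seeded synthetic generators (rigid
    rotors with prescribed principal moments, exact inverse-cube basis-set
    convergence series) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
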