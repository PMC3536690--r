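---
title: "CoMFA 3D-QSAR with comfar: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CoMFA 3D-QSAR with comfar: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(comfar)
```

## The problem and the model

Comparative Molecular Field Analysis (CoMFA) relates the biological activity
of a congeneric small-molecule series to the steric and electrostatic fields
the molecules project into the space around them. The workflow implemented
here is the classic one:

1. each compound gets one 3D conformer with Gasteiger partial charges;
2. the series is rigidly superimposed onto a reference compound by a
   least-squares fit of a shared substructure core;
3. a regular lattice is laid around the aligned series and a probe atom
   (sp3 carbon, +1.0 e, van der Waals radius 1.52 Å) is evaluated at every
   lattice point, giving a truncated Lennard-Jones steric energy
   $E_s = \sum_i \varepsilon_{ij}\left[(R_{ij}/r)^{12} - 2 (R_{ij}/r)^{6}\right]$
   (capped at +30 kcal/mol) and a Coulomb electrostatic energy with
   distance-dependent dielectric $\varepsilon = r$,
   $E_e = \sum_i 332\, q_i q_{probe} / r^2$ (clipped to ±30 kcal/mol);
4. the compounds × (points × 2 fields) energy matrix is filtered
   (minimum-sigma), block-scaled (CoMFA-std) and regressed on pIC50 by NIPALS
   partial least squares;
5. predictivity is assessed by leave-one-out cross-validation
   ($q^2 = 1 - \mathrm{PRESS}/SS_{tot}$, $\mathrm{SDEP} = \sqrt{\mathrm{PRESS}/n}$),
   an external test set, and y-scrambling;
6. coefficient × standard-deviation maps are thresholded into
   favored/disfavored contour regions per field.

The central modeling assumption is linearity: activity is an affine function
of the sampled field values, with the PLS latent variables absorbing the
massive collinearity of neighboring lattice points.

## The packaged dataset

The package ships a 46-compound series of cytotoxic
3,5-diaryl-4,5-dihydropyrazoles (30 training carbothioamides D1–D30, 16
test-set acetyl analogs F1–F16) with IC50 values against the EAC tumor cell
line, transcribed together with the study's own per-compound predicted values
and model statistics. No machine-readable structures were published, so the
SMILES were encoded from the systematic compound names; the packaged table's
acceptance gate is the characterization cross-check
(`validate_characterization()`): every SMILES must reproduce the printed
molecular formula, the `[M+H]+` m/z and the calculated %C/%H/%N.

Known inconsistencies in the printed source data, kept verbatim rather than
"corrected": 14 MS values of polyhalogenated compounds are integer nominal
masses rather than monoisotopic `[M+H]+` (≈0.9 Da below the value the
formula demands); D29's %N disagrees with D22's for an identical formula;
the printed residuals of rows D18, D26 and F10 are inconsistent with their
own observed/predicted entries; and several training-set pIC50 values do not
equal −log10(IC50 µM) although all checkable test-set values do (which fixes
the µM convention used for `pic50_from_ic50()`). Reported values live in
`pic50_reported` and are never recomputed over.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| lattice spacing | 2.0 | Å | the customary CoMFA resolution; finer grids add collinear columns, not information |
| lattice margin | 4.0 | Å | walls extended beyond all atoms in every direction |
| probe charge / radius | +1.0 / 1.52 | e / Å | sp3 carbon probe convention |
| probe well depth | 0.107 | kcal/mol | sp3 carbon entry of the embedded Tripos-style table |
| energy cutoff | 30.0 | kcal/mol | truncation of steric, clipping of electrostatic energies |
| minimum sigma | 2.0 | kcal/mol | drop columns whose sd over compounds is below this |
| components | 6 | – | the component count of the reproduced analysis; `select_components()` picks by LOO q² otherwise |
| contour levels | 80/20 | % | favored/disfavored percentiles of the coef·sd map (70/30 offered as the alternate convention) |
| embedding seed | any integer | – | the only source of randomness in the 3D pipeline |

Atom parameters (radius, well depth per element; combination rules arithmetic
for radii, geometric for well depths; Coulomb constant 332.0 kcal·Å/(mol·e²))
are printed by `vdw_params()`.

## Numerical and design choices

* **One seeded conformer per molecule.** The original analysis used a
  commercial conformer ensemble with manual alignment adjustments that cannot
  be reproduced from the publication. The package replaces it with one
  deterministic distance-geometry conformer (ETKDG, fixed seed, MMFF
  relaxation) per compound — identical input and seed give bit-identical
  output. This is the main reason headline statistics are reproduced only
  qualitatively (see below).
* **Racemic C5.** The ring C5 is an unspecified stereocenter. The embedding
  backend assigns one consistent tetrahedral configuration to it across the
  whole series, so that all C5 substituents fall on the same side after core
  alignment; the racemate is represented by a single enantiomer, and no
  stereo enumeration is performed. Without this, mirror-image ring puckers
  split every substituent region in two.
* **Alignment.** The shared core is the 4,5-dihydropyrazole ring plus its C3
  and C5 aryl attachment atoms and the exocyclic N1 carbon (8 atoms).
  Substructure matching ignores bond orders and breaks symmetric-match ties
  by the lexicographically smallest atom-index sequence; superposition is the
  Kabsch SVD solution with reflections disallowed.
* **Excluded-point electrostatics.** At lattice points where a compound's
  steric energy hits the truncation cap the Coulomb value is meaningless; it
  is replaced by the column mean over non-excluded compounds (the classic
  convention; configurable off). Prediction rows reuse the training-column
  means.
* **Leakage-free cross-validation.** Column filtering and block scaling are
  re-estimated inside every LOO fold; SS_total is taken about each fold's
  training mean by default (`ss_total = "global"` gives the whole-sample
  convention). PRESS is oracle-checked against an explicit refit loop.
* **NIPALS determinism.** With a univariate response the weight vector of
  each component is exactly the X'y direction, so no iteration and no random
  initialization exist; scores are orthogonal by construction.
* **Contour percentiles.** Nearest-rank, no interpolation; the lower tail
  uses the mirrored rank so that a sign-symmetric coef·sd distribution gives
  thresholds symmetric about zero.
* **Degenerate inputs.** A probe on top of an atom returns exactly the
  truncation value (no division error escapes); collinear point sets are
  rejected in superposition; all-masked tables, zero-variance responses and
  rank-exceeding component counts raise informative errors.
* **Charge model.** Gasteiger PEOE with the published orbital
  electronegativity parameters, 8 damped iterations, formal charges as seed.
  Simplifications: amide/thioamide nitrogens are typed sp3, divalent and
  thiocarbonyl sulfur share one parameter set. Net charge is conserved
  exactly by construction.

## What the synthetic generators emulate — and what they do not

`simulate_field_dataset()` produces an energy-like matrix whose columns come
in correlated blocks sharing a latent "region" factor (ρ = 0.7), mirroring
the spatial correlation of neighboring lattice points, with heterogeneous
column spreads (0.5–8 kcal/mol) clipped at ±30. One block carries the signal:
`y = Xβ + ε`. This is the structure under which PLS is *supposed* to work; a
green planted-signal test (q² ≥ 0.7 at 5% noise, scrambled labels ≤ 0.2)
establishes that the estimator recovers a localized linear field signal, not
that any real assay behaves this way.

`simulate_congeneric_series()` grows apolar para-substituents of known
nominal volume (a documented constant table, not computed volumes) on the
dihydropyrazole scaffold and sets activity = slope · volume + noise
(defaults: 0.02 log units/Å, noise 0.1 log units, i.e. about two log units of
dynamic range like the real series). Because the planted mechanism is purely
steric, the fitted model must be steric-dominated and its favored steric
contours must cluster at the substituted position — a ground-truth recovery
test for the entire 3D pipeline. It does not emulate assay error structure,
electrostatic mechanisms, or scaffold flexibility.

## Reproduction scope and known limitations

The published headline statistics (r² = 0.895, q² = 0.568, steric/
electrostatic contributions printed as 0.454/0.546 in the summary table but
73.8%/26.2% in the text, external r² = 0.469) depend on undisclosed
commercial-software internals — conformer selection, manual alignment
adjustments, exact scaling defaults. They are therefore *recorded alongside*
the achieved values, not asserted. A representative run (`run_comfa(seed =
42)`) achieves r² ≈ 0.79, q² ≈ 0.26, contributions ≈ 0.72/0.28 (closer to
the text's 73.8/26.2 than to the table) and external r² ≈ 0.09; the degrees
of freedom (6, 23) and all transcription-level arithmetic reproduce exactly.
External-set prediction is a genuine extrapolation here: the test compounds
carry an acetyl instead of a thioamide cap, and the model is trained on the
study's verbatim training pIC50 column, which has its own inconsistencies.

Other limitations: no hydrophobic or hydrogen-bond fields (CoMSIA-style), no
conformer ensembles or flexible alignment, no region focusing, no
applicability-domain estimation, no hypothesis generation or scoring (the
packaged five-feature hypothesis — 2 hydrogen-bond acceptors + 3 hydrophobic
centers — is derived from the aligned reference compound D5 and used for
mapping diagnostics only).
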