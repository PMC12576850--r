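---
title: "Evaluating metal sites in cryo-EM maps: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating metal sites in cryo-EM maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qrsite)
```

## The problem and the model

Cryo-EM maps at 2–2.6 Å resolve the overall fold well, but metal ions are
refined against restraint libraries that carry almost no information about
metal coordination — in practice only a short-range van der Waals repulsion.
A metal can therefore be "overfitted" into density that belongs to a water,
or split across two positions, without any restraint objecting. `qrsite`
addresses this by swapping the restraints of a small carved region for an
energy from a chemically aware engine and re-refining only that region
against the fixed experimental map.

The combined target is

$$T \;=\; w_x\,T_\mathrm{map} \;+\; w_\mathrm{QM}\,E_\mathrm{region}
\;+\; \bigl(T_\mathrm{restr}-T_\mathrm{restr,region}\bigr)
\;+\; \sum_{i \notin \mathrm{region}} \frac{|x_i-x_i^0|^2}{\sigma_\mathrm{ref}^2}.$$

* $T_\mathrm{map}$ is the negative sum of interpolated experimental density
  at the moving atoms, each weighted by occupancy times the element's total
  electron scattering amplitude relative to carbon. The experimental map is
  z-score normalised internally and never recomputed from the model (cryo-EM
  maps are not model-biased), so every score refers to the same fixed field.
* $E_\mathrm{region}$ is the engine energy of the carved region, including
  its hydrogen link atoms; link-atom forces are redistributed onto both host
  atoms by the exact chain rule of the link-atom placement.
* $T_\mathrm{restr}$ is the dimensionless (sigma-normalised) stereochemical
  term. Terms lying entirely inside the region are removed (the engine
  replaces them); terms straddling the boundary are kept.
* The self-reference term ties all refined atoms outside the region to their
  starting coordinates.

Energy units are handled explicitly: engines declare kcal/mol or kJ/mol,
$w_\mathrm{QM}$ is in mol/kcal, and strain energies are reported in kJ/mol
(1 kcal = 4.184 kJ). A kJ/mol engine with the conversion applied produces an
identical refinement trajectory; the test suite asserts this.

## Key tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `w_x` | 10 (or scanned) | – | map-vs-restraint balance; working values for site-scale refinement are small (single digits to tens) |
| `w_qm` | 7.5 | mol/kcal | makes engine energies commensurate with dimensionless restraints |
| `coordinate_macrocycles` | 3 | – | full minimisations to tolerance |
| `adp_macrocycles` | 1 | – | isotropic-B refinement, coordinates frozen |
| `self_reference_sigma` | 0.01 | Å | surroundings effectively pinned to the start |
| `mask_radius` | 2.0 | Å | RSCC mask around atoms; configurable and recorded with every score |
| coordination cutoff | 2.6 | Å | a ring N within this distance of a metal counts as coordinating |
| link X–H length | 1.09 (C), 1.01 (N), 0.96 (O) | Å | fixed constants keep energies comparable across interpretations |

A "macrocycle" here is one full quasi-Newton minimisation to tolerance; the
inner scheduling of production refinement programs is deliberately not
reproduced. Conformation-dependent, secondary-structure and Ramachandran
restraints are absent by design — site-scale refinement runs at the end of a
structure determination, when the fold is settled.

## The weight scan and the ranking rule

`weight_scan()` refines the site once per grid value of $w_x$ (default ten
values spanning 0–100) and records the average RSCC and strain energy.
The selected weight is the highest value reached before strain starts to
increase (more than 10% relative, `rel_tol`) or average RSCC starts to
decrease (more than 0.01, `abs_tol`), scanning upward; a flat table selects
the grid maximum. An absolute slack of 1 kJ/mol (`strain_floor`) is applied
to the strain comparison: at small weights the refined site sits near the
engine optimum where strain is almost zero, and a purely relative criterion
would fire on chemically meaningless sub-kJ fluctuations. The rule exists in
the literature only qualitatively; these three tolerances are this package's
quantification.

`compare_interpretations()` refines every candidate interpretation of a site
with identical configuration (identical $w_x$, protocol and seed — ranking
runs with differing $w_x$ cannot arise by construction) and ranks them:

1. variants whose average RSCC is within `rscc_tol` (default 0.05) of the
   best form the comparable set; within it, lower strain wins;
2. strains closer than `strain_tol` (default 2 kJ/mol) count as tied and are
   ordered by RSCC.

The second clause exists because a *wrongly* assigned interpretation is
refined under its own engine and relaxes toward that engine's optimum: its
residual strain can be nearly as low as the correct variant's, while the
disagreement with the map shows up as an RSCC drop (for example, a spurious
second copper pushed out of the density by metal–metal repulsion, its B
inflated to the clamp). Strain stays primary — large strain differences are
decisive regardless of small RSCC differences, matching how such comparisons
are read in practice — and both values are always displayed; no single
scalar collapses them. Chemically anomalous geometry (metal–carbon contacts,
metals without any ligand at bonding distance) is additionally flagged, and
oxidation-state calls should be read as flags, not hard assertions: closely
spaced strains may indicate a mixture of redox states in the real sample.

## The surrogate engine

The built-in engine is a harmonic surrogate for a quantum-chemical
description, built per region at construction time:

* ligand-internal bond and 1–3 springs (k = 300 / 60 kcal mol⁻¹ Å⁻²), with
  reference lengths taken from idealised fragment templates (imidazole,
  carboxylate, amide, water) so that the reference geometry is chemically
  ideal rather than whatever the input model happens to contain;
* metal–donor springs with oxidation-state-dependent reference lengths
  (Cu(I)–N 1.90 Å, Cu(II)–N 2.00 Å, Cu(I)–O 2.15 Å, Cu(II)–O 2.05 Å) over
  N/O/S atoms within 2.9 Å at construction;
* angular preferences: linear two-coordination for Cu(I), square-planar-like
  90°/180° donor–Cu–donor terms for Cu(II);
* hydrogen-bond springs (ideal H···A 1.85 Å, k = 10) for polar hydrogens;
* a one-sided short-range repulsion below 0.75 × the vdW-radius sum, with a
  3.0 Å minimum approach for metal–metal pairs — unbridged closed-shell
  Cu···Cu contacts below ~3 Å are strongly repulsive, and this is the term
  that penalises dinuclear interpretations of mononuclear density.

The engine satisfies the general engine contract (exact analytic gradient,
rigid-motion invariance, zero energy at its own reference geometry), and the
same contract battery runs against any user-supplied engine. An adapter
*configuration* for external quantum-chemistry programs is provided
(`external_engine_config()`, defaulting to a meta-GGA functional with
dispersion, a small split-valence basis, and an optional dielectric-4
continuum), but no external program is bundled, invoked or required.

What the surrogate cannot do: it has no electronic structure, so it cannot
discover new bonding patterns (proton transfers, unexpected coordination by
atoms outside its construction-time term list), and its absolute strain
energies are not comparable to quantum-chemical ones. It is a vehicle for
the pipeline's *logic* — relative strains of competing interpretations of
the same density — not for chemistry production work.

## Strain energy

`strain_energy()` reports, in kJ/mol: the engine energy at the model
coordinates after relaxing only the added hydrogens (heavy atoms and link
hydrogens fixed), minus the energy at the optimum with everything free
except the link hydrogens. Fixing the link atoms prevents the relaxed state
from drifting into conformations unreachable inside the protein, which also
means strain values grow with region size and charge and are comparable only
within one site. The relaxed state is the engine optimum under the same
constraints, so the difference is non-negative up to optimiser tolerance; on
a single harmonic spring it equals $k\,\Delta^2$ exactly, which the tests
assert in closed form.

## Numerical choices

* **Optimiser.** A self-contained BFGS (inverse-Hessian update) with Armijo
  backtracking; gradient-component tolerance 10⁻³ target-units/Å, iteration
  cap 400 per macrocycle (2000 for free geometry optimisation). Accepted
  steps never increase the target; fixed atoms are returned bit-identical.
* **Map interpolation.** `interpolate_map()` defaults to trilinear
  interpolation (exact at nodes, flagged zero outside the support — atoms
  outside the map must not be driven by extrapolated density). The
  *refinement target*, however, evaluates the map with separable Catmull-Rom
  cubic convolution: a piecewise-trilinear target has gradient
  discontinuities on voxel faces, and a density maximum pins atoms onto
  those kinks where no descent direction exists, stalling any quasi-Newton
  method. The cubic interpolant is C¹, exact at nodes, and restores clean
  convergence; both interpolants are exposed and tested.
* **Restraint ideals.** The topology builder takes bond/angle ideal values
  from the fragment templates where the residue is templated, falling back
  to the input geometry (self-restraint style) with sigmas 0.02 Å / 3°;
  torsion terms are supported by `restraint_energy()` but not emitted by
  default — at site scale the engine term and angle restraints make them
  redundant. Metal-involving nonbonded pairs get a reduced minimum approach,
  reflecting that metal sites are essentially unrestrained apart from
  short-range repulsion.
* **ADP refinement.** Per-atom isotropic B minimises the squared residual
  between the rendered model map and the experimental map over the region
  mask, after an optimal affine (scale + offset) match; B is clamped to
  [2, 200] Å² and clamping is flagged — a B driven to the upper clamp means
  the map offers no support for the atom.
* **Degenerate inputs.** Empty RSCC masks give an undefined (NA) score,
  excluded from averages and logged; out-of-support atoms contribute zero to
  the map term and are flagged once per refinement; coincident link hosts
  and unresolvable selectors raise typed errors.

## The synthetic-data generator

`generate_toy_site()` builds archetypal sites — a linear bis-histidine
Cu(I) site, a T-shaped His₂/Asp Cu(II) site, a three-histidine brace, a
hydrogen-bonded water cluster with no metal, and a carboxylate-bridged
dinuclear site — at the surrogate engine's reference geometry, inside a
frozen 40-atom carbon scaffold. `simulate_map()` renders the truth with an
extra blur B added to every atom and i.i.d. Gaussian voxel noise. Defaults
are fixed once: voxel 0.5 Å; blur B = 22 Å², which by the $B \approx 4d^2$
rule of thumb corresponds to ~2.35 Å, the middle of the 2.1–2.6 Å range
typical of current cryo-EM structures of such systems; noise 10% of the
clean map's standard deviation, a visually realistic contrast for
well-resolved sites.

`make_scenario()` packages the ambiguity cases the decision layer exists
for: a correct metal site perturbed by 0.3 Å RMSD (per-residue rigid shifts
plus small jitter — model errors misplace whole groups rather than
scrambling internal geometry; backbone stubs and scaffold stay put because
site re-refinement happens after the fold is settled), a copper modelled on
what is truly a water peak, a mononuclear site modelled as dinuclear with a
2.3 Å Cu–Cu distance, and a correct geometry with the wrong oxidation state.

What passing tests on these scenarios show — and do not show. They show the
pipeline's decision logic is sound: given density whose ground truth is
known and an engine whose reference chemistry matches that truth, the true
interpretation wins by strain at comparable RSCC in ≥ 90% of seeded
replicates. They do not show that real deposited sites will be classified
correctly: real maps have correlated noise, anisotropic resolution and
radiation-damage artefacts the generator does not emulate, and real
energetics need a quantum-chemical engine through the adapter interface.

## Problem sizes

Synthetic maps are ~30–40³ voxels at 0.5 Å; carved regions are 15–30 atoms
with 2–5 link hydrogens; refinements converge in a few hundred BFGS
iterations. A full interpretation comparison takes seconds, and the entire
test suite plus acceptance script runs in minutes on one core — sizes chosen
so the statistical checks (10 seeds per scenario kind) stay routine.

## Known limitations

* The surrogate engine's donor list is fixed at construction: a ligand that
  *would* coordinate after a large rearrangement is invisible to it.
* Occupancies are never refined; partially occupied sites are scored as
  modelled.
* No symmetry handling, half-maps, sharpening or FSC; the input map is taken
  as the experimental truth.
* Strain energies are engine-relative; only differences between
  interpretations of the same region are meaningful.
* The calibrated multi-measure site-validation checks of dedicated metal
  validation servers are out of scope; `geometry_report()` provides plain
  distances, angles, coordination numbers and flags instead.
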