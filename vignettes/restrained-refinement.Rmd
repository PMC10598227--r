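---
title: "NOE restraints, restrained refinement and ensemble validation"
author: "noetools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NOE restraints, restrained refinement and ensemble validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noetools)
```

## The model

Solution-NMR structures of protein–ligand complexes are computed from
soft geometric restraints rather than from data that determine
coordinates directly. This package implements the restraint layer of
that calculation and the statistics used to judge the result.

Three restraint types are covered.

* **NOE distance restraints.** Cross-peak intensities are binned into
  four classes — strong, medium, weak, very weak — carrying fixed
  interproton bounds of 1.8–2.8, 1.8–3.5, 1.8–5.0 and 1.8–6.0 Å. The
  1.8 Å floor is the van der Waals contact distance of two protons and
  is common to all classes. `classify_intensity()` is the class table;
  `intensity_for_distance()` is its inverse (the tightest class whose
  upper bound covers a distance).
* **Hydrogen-bond restraints.** Each hydrogen bond, typically inferred
  from H/D-exchange protection plus preliminary structures, contributes
  exactly two restraints: H–O at 1.7–2.5 Å and N–O at 2.7–3.5 Å
  (`make_hbond_restraints()`), so n bonds give 2n restraints.
* **Dihedral restraints.** Backbone φ/ψ predictions with uncertainties
  (TALOS-style) become restraint bands centred on the predicted angle
  with half-width `max(20°, 1.5·sd)` (`talos_to_dihedrals()`). The 20°
  floor prevents over-tight bands where the chemical-shift evidence is
  strong; records at chain termini that lack the flanking backbone atom
  are skipped and reported.

### Ambiguous restraints and the two r⁻⁶ conventions

Degenerate protons (methyls, unresolved methylenes, aromatic pairs) are
addressed by trailing-wildcard pseudoatom selectors such as `HD1*`. A
restraint between wildcard selectors expands to the Cartesian product of
the matched protons, and the pair distances collapse to one effective
distance in either of two conventions:

$$d_\mathrm{avg} = \Big(\tfrac1N\sum_p d_p^{-6}\Big)^{-1/6}, \qquad
  d_\mathrm{sum} = \Big(\sum_p d_p^{-6}\Big)^{-1/6},$$

related exactly by $d_\mathrm{avg} = N^{1/6} d_\mathrm{sum}$, so the
summed form is never larger. Refinement protocols and deposited-model
validation reports do not agree on the convention, which can make a
structure refined violation-free under averaging appear violated in a
report computed with summation **or vice versa: because
$d_\mathrm{sum} \le d_\mathrm{avg}$, summation produces *fewer*
upper-bound violations on the same coordinates, so a report that flags
more of them under summation must differ in some further convention
(e.g. in how pseudoatom bound corrections were applied).** The package
takes no side: `violation_report()` computes both in one pass and
reports them side by side.

## The potential and the refiner

The restraint energy is a flat-bottom soft-square: zero inside the
bounds; $k_\mathrm{noe} v^2$ for a violation $v$ up to a switch $s$;
beyond $s$, linear with matched value and slope $2 k_\mathrm{noe} s$.
Energy and first derivative are continuous everywhere (checked
numerically in the tests). Dihedral restraints are harmonic in the
wrapped excess violation, in radians. Covalent geometry is enforced by
harmonic bond, angle and improper terms whose equilibria are *measured
from the reference structure*, so the reference is the exact minimum of
the covalent energy. All ligand covalent terms are multiplied by a
scale factor, default 0.2 — strong enough to hold the ligand together,
weak enough not to dominate the restraint forces.

Defaults (all configurable through `energy_model()` and the topology
tables): $k_\mathrm{noe} = 50$ /Å², $k_\mathrm{dihedral} = 200$ /rad²,
switch 1.0 Å, bonds 1000 /Å², angles 100 /rad², impropers 50 /rad²
(protein). The absolute energy scale is arbitrary; only orderings and
violation statistics are meaningful, which is why published
calorie-denominated NOE energies from torsion-angle annealing engines
are not comparable with this surrogate.

`minimize_structure()` is a steepest-descent minimizer with a
Barzilai–Borwein initial step and an Armijo backtracking line search;
the energy over accepted steps is monotone non-increasing and the
analytic gradient is validated against central finite differences to
1e-5 relative. Descent alone can stall in local minima (typically a
flipped backbone torsion trapped on the wrong side of its harmonic
band); the minimizer therefore performs up to `restarts` noise-injection
restarts — re-perturb the current best by `restart_noise` (0.5 Å RMS)
and re-descend, keeping the lower-energy outcome — whenever the result
still sits above `restart_threshold` (1.0 energy units, i.e. essentially
unconverged). This is the Cartesian stand-in for the basin hopping that
simulated annealing provides in production structure calculation;
dynamics itself is out of scope.

`refine_ensemble()` (the package's fitting entry point, returning a
classed object with `print`/`summary`/`plot` methods) runs a pool of
independent perturb-and-minimize calculations — run $r$ is seeded with
`seed + r`, so pools are bit-reproducible — and keeps the `keep_n`
structures with the lowest NOE energies, with stable run-index
tie-breaking, mirroring the "N structures with the lowest NOE energies"
selection rule of published protocols.

## The enantiomer screen

When the active hand of a chiral ligand is unknown (racemic material),
separate calculations are run with R and S topologies, which differ
only in the sign of the chirality-enforcing improper targets; bond and
angle terms are mirror-invariant. `enantiomer_screen()` compares the
`n_lowest` NOE energies per hand (winner: lower mean) and evaluates
`chirality_sign()` — the signed tetrahedral volume over caller-supplied
substituent priorities; no CIP inference — on every refined structure,
flagging runs whose final hand differs from their topology
("inversions"). With deliberately softened impropers the NOE pull does
flip a wrong-hand ligand, which is exactly the failure mode the flag
exists to catch; with the rigid default topology the wrong hand is held
and pays its NOE penalty instead.

The screen's protocol here is a pool of 4 runs per hand at 1.0 Å RMS
perturbation, iteration-capped descent, and comparison of the 2 lowest
NOE energies; the margin between hands combines the intrinsic misfit of
the mirrored ligand with the optimization difficulty of reaching its
best pose, just as annealing-pool energy comparisons do. Noise-injection
restarts are disabled inside the screen so both hands are scored under
the same iteration-capped protocol; giving the wrong hand extra basin
hopping would only let it polish a pose the restraints cannot actually
distinguish at full convergence, eroding the comparison the screen is
designed to make.

## The synthetic complex

`make_fixture()` generates the study conditions the tests assume:

* a 30-residue amphipathic sequence built as an ideal α-helix
  (φ = −57°, ψ = −47°, trans peptide bonds, ideal bond geometry) with
  side chains reduced to Cβ plus an `HB1/HB2/HB3` pseudo-methyl on
  methyl-bearing residue types — the restraint machinery needs names and
  positions, not rotamer chemistry;
* a rigid toy ligand: 8 heavy atoms around one tetrahedral
  stereocenter, two methyl groups, a hydroxyl and an amide-like arm,
  docked with its proton-rich face against the helix at a minimum
  heavy-atom contact of 3.0 Å (11 intermolecular restraints at the
  default 5.0 Å cutoff). R and S builds are exact mirror images. Ligand
  impropers are measured from the built geometry with two impropers per
  tetrahedral centre — one improper alone leaves the fourth substituent
  free to flip through the plane of the other three at modest angle
  strain, which would silently invert the hand — and a stiff force
  constant (2500, i.e. 500 after ligand scaling) so the ligand behaves
  as the rigid chiral body the screen assumes;
* restraints derived from the true coordinates by the generative rule
  "tightest class whose upper bound covers the r⁻⁶-averaged true
  distance", with helical i→i+4 hydrogen bonds and φ/ψ bands of 20°
  half-width. Proton-group pairs whose r⁻⁶-summed distance falls below
  the 1.8 Å floor (geminal/vicinal contacts, which NOE analysis never
  restrains) are excluded, so the truth satisfies every restraint under
  *both* conventions — the zero-violation ground-truth contract. The
  optional bound noise is half-normal and widens bounds only;
* Gaussian-perturbed starting structures (per-atom RMS 1.0 Å by
  default; per-coordinate σ is RMS/√3).

What the generator does *not* emulate: spectral overlap, spin
diffusion, mis-assignment, assignment ambiguity beyond wildcard
pseudoatoms, real side-chain rotamers, solvent or non-bonded physics.
Passing tests therefore demonstrate that the restraint arithmetic,
refinement and validation machinery are correct and self-consistent —
not that the surrogate would reproduce a particular experimental
structure from real peak lists.

## Numerical choices

* Angles wrap into (−180°, 180°]; torsions use the IUPAC sign
  convention; coordinates are Å; residue numbers are 1-based and taken
  from the coordinate file (no renumbering between construct and native
  numbering — e.g. a chimera residue 165 corresponding to native
  residue 206 is reported as 165, with the offset left to the user).
* Superposition is Kabsch via SVD with a determinant correction, so the
  rotation is always proper; the RMSD is defined from two atoms up, a
  unique rotation from three non-collinear atoms. Ensemble RMSD is
  *average pairwise*: every model pair is superposed independently on
  the stated selection (backbone = N, CA, C, O by default, with an
  N/CA/C variant available), not against a mean structure.
* The chirality tolerance (triple product magnitude 1e-4 Å³) guards the
  planar/indeterminate case.
* Pseudoatom expansion order is file order; pool selection breaks
  energy ties by run index; all RNG is Mersenne-Twister with explicit
  seeds, and seed arithmetic is documented next to each use
  (`seed + run_index` for pool runs, an offset stream for restarts).
* Violation summary statistics report the mean and s.d. over the
  per-model average violations (the usual structure-table convention);
  the per-cell alternative is also computed, since published tables
  rarely state which was used.
* Problem sizes used by the tests and the acceptance script: the
  default 30-residue fixture (about 230 atoms, ~270 restraints), pools
  of 4–10 runs, 20 recovery seeds and 10 screen seeds — sizes chosen so
  a complete run is a desk-scale computation on one CPU.

## Known limitations

* The CNS-style parser supports the single
  `assign (selector) (selector) d dminus dplus` form; deposited
  restraint files using other statements or pseudoatom dialects are
  skipped restraint-by-restraint in `violation_report()` rather than
  failing, and unsupported files should be converted externally.
* The refiner is a minimizer, not a dynamics engine: absolute energies
  are not comparable to torsion-angle annealing outputs, and only
  orderings, violations and geometric statistics transfer.
* Intra-ligand restraints have no defined category and are rejected by
  `categorize()`.
* `read_structure()` trusts the deposited atom naming; no automatic
  pseudoatom-nomenclature translation is attempted beyond trailing-`*`
  matching.
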