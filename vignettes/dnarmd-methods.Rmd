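---
title: "Methods: NOE-restrained refinement of DNA bis-intercalator complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NOE-restrained refinement of DNA bis-intercalator complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models it
implements, the parameters that matter, what the synthetic-data
generators do and do not emulate, the numerical choices, and the known
limitations. It states no empirical result that the test suite and
acceptance script do not themselves compute.

## 1. The distance-calibration model (ISPA)

Under the isolated-spin-pair approximation a NOESY crosspeak volume
between protons *i* and *j* is proportional to $r_{ij}^{-6}$. Volumes are
referenced to the cytosine H5–H6 crosspeak, a covalently fixed distance
of 2.45 Å, so

$$ r = r_\mathrm{ref}\left(\frac{V_\mathrm{ref}}{V}\right)^{1/6}, $$

with flat bounds at $\pm 20\%$ of $r$. `calibrate()` implements exactly
this; spin diffusion is deliberately ignored (a full relaxation-matrix
treatment is out of scope), which on real data biases long distances
short — the synthetic generator uses pure ISPA, so this bias does not
appear in the tests, and a green round-trip test establishes correctness
of the arithmetic, not robustness to spin diffusion.

Unresolved groups are represented by pseudo-atoms at the group centroid.
Upper bounds are inflated by standard corrections (+1.0 Å for a methyl;
+0.9 Å for a non-stereoassigned methylene and +2.0 Å for equivalent
aromatic pairs are supported but unused by the default generators, which
model methyls only).

The internal base templates place the aromatic C–H bond at 1.07 Å so
that the cytosine H5–H6 distance is exactly 1.38 + 2·1.07·sin30° =
2.45 Å; the calibration ruler is therefore exact by construction and the
noise-free round trip recovers true distances to numerical precision.

## 2. Geometry: duplex, gaps, ligand

`build_bdna()` constructs uniform fiber-geometry B-DNA (default rise
3.4 Å, twist 36°/step) from planar regular-polygon base templates
expressed directly in the base-pair reference frame (origin at the pair
centre, x toward the major groove, y along the long pair axis, z the
helix axis). The complementary residue is the 180° rotation about x of a
"plus" template, which makes the duplex exactly antiparallel. The 5′
phosphate of each residue is placed by the inverse canonical step applied
to the previous residue's O3′, so backbone continuity (O3′–P = 1.6 Å) is
exact on both strands of an unperturbed build. Sequence-dependent fine
structure (propeller, roll, sugar repuckering) is a non-goal.

`make_ground_truth()` opens intercalation gaps by enlarging the rise and
reducing the twist of the listed steps; optional neighbour unwinding
(default on, 4.5°/neighbour step) mirrors the observation that drug
unwinding spreads into the ±1 steps. The default TFF1 world places gaps
at steps 5, 7, 9, 11 with rises 5.95, 6.01, 6.34, 5.86 Å and per-gap
unwinding 11.5, 11.5, 9.5, 9.5°, so that the two 3-step binding sites
unwind by exactly 32° and 28° including neighbour contributions. The
inter-site step 8 receives two neighbour contributions (9°), slightly
above the ~7° reported for the real complex; the difference is within
the qualitative "4–5° per neighbour" rule this generator encodes.

The bis-intercalator is encoded from its chemical connectivity: two
planar phenazine tricyclics (aromatic H2/H3/H4 and H6/H7/H8, a C9
methyl, a carboxamide at C1) joined by an aminoalkyl linker whose two
γ-amino nitrogens are protonated at pH 7. The carboxamide nitrogen leans
toward the ring N10 at 2.7 Å, the intramolecular hydrogen-bond geometry
characteristic of phenazine-1-carboxamides. `place_ligands()` rigidly
centres each ring system in its gap (centroid at the midpoint of the
flanking pair origins, plane parallel to the bases) with the linker
threaded through the major groove as a tetrahedral zig-zag along a
Bezier path. After placement the ground truth is relaxed under the bare
force field with the geometry-defining atoms (base heavy atoms, ligand
ring systems) frozen, which removes construction strain without moving
anything the analyzer measures.

## 3. Restraint potential: flat-bottomed analysis, bi-harmonic refinement

Two restraint surfaces coexist, deliberately:

* `restraint_energy()` is the flat-bottomed well used for *analysis*:
  zero inside `[lower, upper]`, $k\,s_u (d-u)^2$ above and
  $k\,s_l (l-d)^2$ below, with $k$ = 30 (NOE) or 60 (hydrogen bond)
  kcal·mol⁻¹·Å⁻² and a configurable skew. Violation statistics (counts
  beyond 0.2 Å, RMS excess) are always measured against the bounds.
* The *refinement engine* uses the skewed bi-harmonic well centred on
  the calibrated target distance: $k\,s_u (d-r)^2$ above $r$ and
  $k\,s_l (d-r)^2$ below. This is the classic X-PLOR biharmonic NOE
  potential. The distinction matters: with purely flat wells nothing
  centres a distance inside its ±20 % bounds, and the intercalation-gap
  rise is under-determined by about ±1 Å (we measured exactly this
  during development); the centred well restores the determinacy the
  published protocol had. The default skew is 1:1 and configurable via
  `restraint_params()`.

Hydrogen-bond restraints (two per selected pair: N1⋯N3 plus one
carbonyl⋯amino pair, targets from the idealized pair geometry, flat
bounds ±0.2 Å) keep the duplex paired at 1000 K. Which 12 of the 15
pairs carry the canonical 24 restraints is not recoverable from the
source data; `tff1_hbond_pairs()` defaults to the non-terminal pairs
minus G11:C20, the pair whose imino proton is least perturbed at the
weak binding site.

Classification uses five categories that always partition a set:
`intraresidue`, `sequential` (any inter-residue DNA–DNA contact — the
NOESY cutoff occasionally captures cross-strand contacts that strict
sequential accounting would orphan), `hydrogen_bond`, `drug`,
`drug_dna`.

## 4. The annealing protocol and the force-field surrogate

`default_schedule()` encodes the staged protocol as data: 300 K/20 ps
with all restraint constants at 1 kcal·mol⁻¹·Å⁻²; 1000 K/3 ps; a 24 ps
linear ramp to the final 30/60; cooling from 1000 K to 300 K in 28
cycles of 25 K, each 1000 steps of 3 fs; 3 ps of equilibration; a 3 ps
coordinate-averaging window; 250 steps of minimization. Heating and
equilibration stages use 1 fs (3 fs is stated only for the cooling
cycles). `scale_schedule(factor = 0.1)` is the desk-scale test default —
same stages, temperatures and force constants, 10 % of the steps; the
full protocol is one argument away.

The force field is a simplified CHARMM-like surrogate, since the exact
CHARMM parameterization is not in scope and bit-reproduction of X-PLOR
is a non-goal:

* Harmonic bonds (k = 300 kcal·mol⁻¹·Å⁻²), angles (50 per rad²) and
  improper/ring torsions (30 per rad²) with ideal values measured from
  the package's own idealized residue templates — the unperturbed build
  is an exact minimum of the covalent terms by construction
  (self-parameterization).
* The inter-residue O3′–P linkage is a flat-bottomed tether (1.5–4.5 Å,
  k = 50 outside). The rigid-residue builder has no backbone torsional
  degrees of freedom, and a stiff bond here would fight gap opening; the
  soft tether stands in for the torsional slack with which real DNA
  absorbs intercalation stretch.
* Nonbonded: soft quartic repulsion $k_\mathrm{rep}(R_m^2 - r^2)^2$ for
  $r < R_m = 0.8 (R_i + R_j)$ (X-PLOR REPEL style; no attraction), plus
  distance-dependent-dielectric electrostatics $E = 332\,q_i q_j / r^2$
  (ε(r) = r) on the formally charged centres. Phosphates carry the
  Manning-condensation effective charge −0.24 e (the standard
  implicit-counterion value; the published charges are unrecoverable),
  protonated linker amines +0.5 e. Exclusions cover 1-2, 1-3 and 1-4
  neighbours.
* Hydrogen masses are repartitioned to 3× physical so the stated 3 fs
  cooling timestep integrates stably without bond constraints; classical
  configurational averages are independent of the masses.

Integration is velocity Verlet with a per-step velocity-rescaling
thermostat (the simplest contract that holds each stage at its
temperature; the logs record the realized mean kinetic temperature per
stage). Initial velocities are Maxwell–Boltzmann draws with seed
`seed + model − 1`, which makes every ensemble member independently
seeded and the whole run deterministic. Divergence (non-finite or
absurd energy) aborts a model, which is flagged in the ensemble info
rather than silently dropped. After the last stage the coordinates
averaged over the 3 ps window are minimized by steepest descent with an
adaptive step cap.

Model selection is lexicographic — fewest violations beyond 0.2 Å,
then lowest total energy, then original index — a documented choice, as
the published weighting between "minimal energy" and "minimal
violations" is not defined. How many candidates to generate before
selecting is likewise open; the tests use 6 candidates → 3 selected,
scaled down from the published 10-from-many for runtime.

## 5. Helical-parameter conventions

A pair frame is obtained by one joint least-squares (Kabsch)
superposition of the idealized two-base pair template — all base heavy
atoms, complement pre-flipped — onto the observed atoms. This deviates
from the per-base-fit-then-average scheme on purpose: fitting each base
separately puts the pair origin ~5 Å outside the fitted atom cloud, so
coordinate noise is levered into ~0.15 Å origin and ~1° twist error on
ensembles with realistic spread, while the joint fit keeps the origin
interpolated and is identical on exact structures (the round-trip tests
cover this). Rise is the projection of the inter-origin vector on the
mean pair normal; twist the signed rotation of the x axis about it;
unwinding is 36° − twist; site unwinding sums steps. Because the
analysis program behind the published numbers is unnamed, small
convention differences (< 0.2 Å, < 2°) are tolerated and the tests use
those tolerances. Pairwise ensemble RMSD defaults to all heavy atoms
(DNA + ligand, terminal residues included; the selection is an
argument).

## 6. Synthetic data: what a green test establishes

The generators emulate: gap geometry imposed exactly (builder
post-conditions are tested to 0.05 Å / 0.5°); *r*⁻⁶ volumes with
multiplicative log-normal noise (default sd 10 %, a typical integration
error; the source is silent); a 5.5 Å observation cutoff (typical NOESY
detection range; also a decision); methyls as centroids; exchangeable
imino protons unobserved (D₂O convention). FID titrations follow the
equal-site model with free drug computed by 2:1 mass balance and
i.i.d. Gaussian replicate noise (assay defaults: duplex 16.7 µM, drug
0–100 µM in 13 points, 3 replicates, 2 % noise).

They do **not** emulate: spectral overlap and linewidths, spin
diffusion, assignment ambiguity or missing peaks, baseline drifts in the
titration, or EtBr competition modelled explicitly (displacement is a
proportional proxy, as in the assay's own analysis). A green
recovery test therefore establishes that the pipeline inverts its own
stated forward model — not that it would survive every pathology of real
spectra.

The "reference ensemble" used by the offline geometry tests is a
labelled synthetic stand-in for the deposited ensemble: the ground-truth
complex jittered per model with per-coordinate sd fixed *a priori* at
$0.78/\sqrt{6}$ Å, the closed-form value for which the expected pairwise
heavy-atom RMSD equals the published 0.78 Å spread. Rises, unwinding and
spread are thus reproduced by construction; the tests verify that the
analysis chain measures them back, which validates the analyzers, not
the deposition. A user-supplied deposited PDB flows through the same
`read_pdb_ensemble()` → `compute_frames()` → `ensemble_stats()` path.

## 7. Numerical choices and degenerate inputs

* Free-ligand mass balance is solved by bracketed root finding
  (`uniroot`, relative tolerance 10⁻¹²) on the monotone map
  $x + 2 T_0 B x/(K_D + x) - X_t$; the naive fixed-point iteration
  diverges whenever $2 T_0 B / K_D > 1$, which holds at the assay
  concentrations. The quadratic closed form is the independent oracle in
  the tests, never the implementation.
* `fit_kd()` minimizes over (log K_D, B) by Nelder–Mead from three
  starts (0.1×, 1×, 10× the initial guess), recomputing free drug each
  iteration; bootstrap CIs use seeded case resampling (default 1000
  resamples where requested; tests use fewer for speed).
* Kabsch superposition forbids reflections (determinant correction);
  fewer than 3 atoms is an error.
* `calibrate()` rejects non-positive volumes with a warning and a
  count; a missing reference peak is an error, as is a cytosine-free
  structure in `simulate_noesy()`.
* Restraint evaluation resolves pseudo-atoms to centroids; the engine
  distributes centroid forces equally over group members.
* Degenerate schedules (zero steps, zero minimization) are exact
  identities, which the tests pin down.
* All seeds are plain R integer seeds; every generator and the annealing
  engine are bit-deterministic on one platform given (inputs, seed).

## 8. Known limitations

* The force-field surrogate has no attractive dispersion term; absolute
  energies are meaningless and only rankings and geometry are
  interpreted.
* Desk-scale (10 %) schedules freeze slightly more thermal noise into
  the final models than the full protocol would; the recovery tests
  budget 0.3 Å for this.
* The sequential/long-range category merge slightly overcounts
  "sequential" relative to a strict adjacent-step definition.
* The linker is modelled without protons and its conformational
  statistics are not validated against anything — it exists to hold the
  two ring systems at the right register and charge.
* Single mixing time only; no relaxation-matrix back-calculation, no
  stereo-assignment inference, no groove-width or full helicoidal
  (roll/slide/propeller) analysis.
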