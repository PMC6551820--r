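---
title: "memmatch: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{memmatch: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memmatch)
```

# The scientific problem

A transmembrane (TM) α-helix buries a hydrophobic stretch inside the
membrane hydrocarbon core. With a canonical helical rise of 1.5 Å per
residue, `n` hydrophobic residues span `1.5 n` Å. When that span differs
from the membrane's hydrophobic thickness the *hydrophobic mismatch* is
positive (peptide too long) or negative (too short), and the system can
respond by tilting the helix, deforming the bilayer locally, partially
unwinding the helix, or altering helix–helix packing through
glycine-anchored motifs such as `GVxxGVxxT` (the Glycophorin A
dimerization motif; `x` is any hydrophobic residue from
A, V, L, I, F, M, G, T). memmatch implements the measurement chain for all
of these observables plus the statistics of cell-based dimerization
assays, validated end-to-end on synthetic ensembles with known ground
truth.

All internal lengths are Å (grid spacing "0.33 nm" is stored as 3.3 Å);
the membrane normal is +z; lateral x/y are treated as periodic
(minimum-image), z is not.

# Dimer geometry

**Tilt.** The motif anchors all selections. The "top" of the dimer is the
mass-weighted center of mass (COM) of the six residues pooled from the
three-residue flanks C-terminal to the two motifs; the "bottom" is the
same on the N-terminal side. Tilt is the angle of the top−bottom vector
to z, folded into [0°, 90°] (`arccos(|v·ẑ|/‖v‖)`): a membrane has
up–down symmetry and no handedness is reported.

**Crossing.** Per chain, a vector joins the COM of the residue
immediately N-terminal of the motif to that of the residue immediately
C-terminal (`anchors = "single"`; a three-residue-triplet variant is
available by argument, since the original tooling's exact reading of
"right next to the motif" is ambiguous). The crossing angle is the
unsigned angle between the two chain vectors in [0°, 180°].

**COM convention.** COMs are mass-weighted over all atoms of the selected
residues; `backbone_only = TRUE` restricts to N/CA/C/O. The mass table is
built in (unknown elements fall back to 12.011 u with a warning) because
coordinate files carry no masses.

**RMSD/RMSF.** `kabsch_superpose()` is the SVD solution with the
determinant sign fix (proper rotations only). `rmsd_series()` fits each
frame to a reference frame (default: the first frame of the supplied
trajectory — the original reference structure of such analyses, an NMR
template model, is not distributable; the reference is configurable) on a
fit selection defaulting to the analysis selection. The `"motif5"`
selection is the backbone of the five *conserved* motif residues
(G, V, G, V, T) per chain: the motif is described both as a 9-position
span and as "5 residues per peptide", and we honor both statements by
using the 9-residue span to anchor flank selections and the 5 conserved
positions for RMSD. `rmsf_per_residue()` fits frames to the
time-average structure (two refinement passes, which is converged for
these systems) and reports per-CA fluctuations.

Equilibrium averages conventionally discard the first part of a
trajectory; `discard_fraction` (default 0.5 where averaging is implied)
generalizes "averages over the last half of the run".

# Helicity (Kabsch–Sander)

The α-content estimator re-implements the DSSP electrostatic model, α
class only: hydrogen-bond energy

```
E = 0.084 · 332 · (1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)   kcal/mol
```

with a bond at `E < −0.5`; a 4-turn at residue *i* requires the bond
CO(i)←HN(i+4); two consecutive 4-turns (at *i−1* and *i*) label residues
*i..i+3* as `H`. 3₁₀/π classes are collapsed into "other": the sequences
under study never leave the α regime, and only α content is reported.
Terminal residues lacking an i+4 partner can never be `H`.

Amide hydrogens, when absent (backbone-only inputs), are placed 1.01 Å
from N along the unit bisector opposing the C(prev)→N and CA→N
directions. Prolines never donate (standard DSSP; the sequences here
contain none). `hbond_energy()` raises an error when any inter-atomic
distance falls below 0.5 Å; inside `assign_alpha()` such clashing
geometries are treated as "no bond" instead, so that strongly distorted
(e.g. thermally melted) frames yield low helicity rather than an error —
an unphysical overlap is not a hydrogen bond.

Helicity denominators use the full chain length as present in the input.
MD-derived helicity percentages of real simulations are not reproducible
at desk scale; the frozen regression value for the default 23-residue
ideal helix is self-generated: residues 1..21 (0-based) are `H`, giving
21/23 ≈ 0.913.

# Membrane maps

`split_leaflets()` freezes the upper/lower assignment on the first frame
(markers above/below the mass-weighted marker midplane); planar bilayers
only, no flip-flop tracking. `thickness_map()` bins marker atoms into a
periodic lateral grid (default spacing 3.3 Å; the grid rounds the box to
whole cells) and takes the time-and-atom mean z per leaflet per cell;
thickness is the difference. Default markers are head-group phosphorus
(`"name P"`, the P–P thickness); the hydrophobic thickness uses the acyl
chain α-carbons, default atom names `C22`/`C32` (the common
glycerophospholipid naming), overridable because "fatty acid chain alpha
carbons" pins down no atom record.

Empty cells are filled from the nearest occupied cell (periodic), by
inverse-distance weighting, or flagged `NA` — the original mapping tools
interpolate but leave the scheme unstated, so nearest-neighbour was
chosen as the least-assuming default.

`bulk_thickness()` quantifies "the grid points furthest away from the
protein" as the occupancy-weighted mean over the top `far_fraction`
(default 0.25) of periodic cell-to-footprint distances; no published
cutoff exists, so the fraction is exposed. The protein footprint is the
time-averaged lateral position of all peptide atoms (maps are
time-averaged, so the reference is too). The bulk reference is computed
on the time-averaged map, not per frame (the per-frame alternative
changes nothing on planar synthetic systems and is noisier).

`hydrophobic_length(n) = 1.5 n` Å and
`mismatch_report()` labels the sign with a 1.0 Å deadband for "matched"
(a sub-Ångström imbalance is below the method's resolution).

# The synthetic generator

The generator builds the *stated world* of the systems it emulates:
200 lipids per leaflet (box area from 68 Å²/lipid, typical fluid-phase
phosphatidylcholine — system sizes are given in lipid counts only),
bilayer thickness pairs mirroring DLPC/DOPC/DEPC
(P–P 31.6/38.7/47.3 Å ↔ hydrophobic 20.0/27.4/35.7 Å, DOPC-like
defaults), leucine-flanked `GVxxGVxxT` peptides, 7 Å inter-axial
separation, and i.i.d. Gaussian thermal noise. Pseudo-lipids are marker
atoms only (one P, two chain α-carbons, vertically aligned): no analysis
in scope reads acyl tails, and no physical dynamics is claimed — the
generator validates estimators, it does not simulate membranes.

**Helix construction.** Backbone N/CA/C/O sit on concentric helices with
exact rise 1.5 Å and twist 100°/residue; the per-atom radii and phase/z
offsets were derived once from a chain built at canonical φ/ψ =
(−57°, −47°) with standard bond geometry. Locking the exact rise/twist
stretches the inter-residue C–N bond slightly (1.36 vs 1.33 Å) — an
accepted artifact for a marker-geometry generator; CA–CA distances
(3.794 Å) and Kabsch–Sander i→i+4 energies (−2.83 kcal/mol, bonded;
i→i+3/i+5 not bonded) remain canonical.

**Tilt semantics (a deliberate design choice).** The dimer-orientation
metrics are COM-segment based, and for a backbone-only ideal helix the
single-residue and triplet COMs lie off the helix axis; the 120° phase
difference between the above/below flank centers leaves a ~1.8 Å lateral
component over an 18 Å span (~5–8°). No rigid placement of two
identical-phase helices makes both the tilt read 0° at truth 0° and the
crossing read 0° at truth 0°. The generator therefore *defines* its tilt
parameter as the orientation of the motif-span vector — exactly the
quantity the tilt metric measures: chains are translation-related (which
makes the crossing exact to ≤ ~0.5° by construction) and the whole dimer
is rigidly rotated so its motif-span vector sits at the configured tilt.
This is a ground-truth definition, fixed before any test was run, not a
calibration knob.

**Noise and determinism.** Per-frame displacements are isotropic,
uncorrelated Gaussians; R's Mersenne-Twister with Inversion normals is
named in the config so regeneration under a seed is bit-identical.
Linear schedules on noise (melting) and tilt are available for trend
tests.

**Assay tables.** Raw signal = effect × normalizer × lognormal noise with
`sdlog = sqrt(log(1 + cv²))` and `meanlog = −sdlog²/2` (mean exactly 1,
so configured effects are recovered unbiasedly); the normalizer is itself
lognormal around 0.5 (OD600-like). Default 6 replicates per pair
(emulating "at least 4 independent replicates" with margin), cv = 0.1.

**What a green test does not establish.** The generator contains no
forces: lipid packing, helix–lipid coupling, dimer dissociation, or real
thermal correlations are absent. Recovery tests certify the estimators
(given a structure with known geometry, the measured numbers are right);
they say nothing about whether real membranes adopt such structures.

# Assay statistics

Normalization is the record-wise ratio raw/normalizer (culture OD600 in
bacterial reporter assays; co-transfected Renilla luciferase in
BiFC-style assays); no blank subtraction is applied (none is used in the
assays emulated). Relative fluorescence scales by the mean of the
positive-control pair, optionally batch-matched. For a hetero pair
(X, Y) the reference set *merges* the X/X and Y/Y homo-dimer relative
values; fold change is mean(X/Y)/mean(reference) and significance is a
two-sample two-sided Student's *t* — pooled variance by default, Welch by
flag, since the source analyses state only "Student's t-test"; tests are
unpaired (pairing by batch is not documented in the emulated protocols).
Degenerate zero-variance comparisons resolve to the limit (identical
means → p = 1, else p → 0).

`bh_adjust()` is the Benjamini–Hochberg step-up
(`q_(i) = min_{j≥i} m p_(j)/j`, capped at 1). The family is all tested
pairs within one analysis, per comparison type (vs. homo reference and
vs. negative control are adjusted separately); the emulated studies do
not state their family, so it is exposed to the caller. Calls at level α
(default 0.05): `dimer` if significantly above the negative control but
not below the homo reference, `reduced` if both, `background` if
indistinguishable from the negative control.

# Numerical choices and degenerate inputs

- Kabsch superposition requires ≥ 3 non-collinear points; reflections are
  excluded via the determinant sign fix.
- Tilt/crossing raise a degenerate-geometry error on zero-length vectors
  (top COM coincides with bottom COM).
- PDB fixed columns follow wwPDB v3.3 (chain from column 22, ≤ 99,999
  atoms — synthetic systems are small); GRO carries no chain labels, so
  the reader accepts a chain map over sequential residue indices and
  defaults to a single chain.
- Angle folding: tilt into [0°, 90°], crossing into [0°, 180°], both
  unsigned.
- Thickness grids round the box to whole cells; spacing must not exceed
  half the lateral box.
- The `matched` deadband of `mismatch_report()` defaults to 1.0 Å.

# Known limitations

- Helix-axis fitting (inertia tensor / cylinder regression) is out of
  scope: the tilt definition is COM-segment based by design.
- Only the α class of secondary structure is assigned; no strand/turn
  classes, no solvent accessibility.
- No curvature, lipid-sorting, area-per-lipid, or order-parameter
  analyses; leaflet assignment assumes planar bilayers.
- The Kabsch–Sander energy is sharp at −0.5 kcal/mol: under strong
  coordinate noise helicity drops quickly (σ = 0.5 Å roughly halves it),
  which is a property of the assignment rule, not a bug.
- Compressed trajectory formats (XTC) are not read natively; convert to
  multi-model PDB/GRO upstream.
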