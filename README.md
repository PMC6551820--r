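# memmatch

Quantitative analysis of **hydrophobic mismatch** in transmembrane (TM)
helix dimerization, for structural bioinformaticians and membrane
biophysicists who need the full measurement chain — from coordinate files
to dimer geometry, membrane maps, and cell-assay statistics — as tested,
scriptable R.

A TM helix of `n` hydrophobic residues spans roughly

```
L_hydrophobic = 1.5 Å × n
```

of the membrane hydrocarbon core (the canonical α-helix rise per residue).
When `L_hydrophobic` differs from the membrane's hydrophobic thickness
`d_membrane`, the **mismatch** `ΔL = L_hydrophobic − d_membrane` is
*positive* (peptide longer than the membrane is thick) or *negative*
(peptide shorter), and the system compensates by helix tilting, local
membrane thinning/thickening, or changes in helix–helix packing through
the glycine-anchored `GVxxGVxxT` dimerization motif (Glycophorin A's).
memmatch quantifies each compensation channel:

- **Dimer geometry** — tilt angle (motif-span vector vs. the membrane
  normal, `arccos(|v·ẑ|/‖v‖)`), crossing angle between the per-helix
  motif vectors, Kabsch least-squares superposition, RMSD and per-residue
  RMSF series.
- **Helicity** — Kabsch–Sander hydrogen-bond energies
  `E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)` kcal/mol with the
  −0.5 kcal/mol bond cutoff and the two-consecutive-4-turns α rule.
- **Membrane maps** — leaflet decomposition, periodic lateral grids
  (default 3.3 Å spacing) of phosphorus–phosphorus or chain-α-carbon
  thickness, far-field bulk reference, perturbation maps.
- **Mismatch calculus** — the 1.5 Å/residue rule and sign classification.
- **Assay statistics** — normalization (fluorescence / OD600 or
  luciferase), relative fluorescence vs. a positive control,
  merged-homodimer fold change for hetero-pairs, Student's *t*,
  Benjamini–Hochberg q-values, and the dimer/reduced/background call.
- **Synthetic ground truth** — ideal helical dimers in planar
  pseudo-bilayers (controllable tilt, crossing, thickness, Gaussian dent,
  thermal noise) and plate-style assay tables, so every estimator is
  validated against known parameters without running molecular dynamics.

Fixed-column multi-model PDB and GRO readers/writers are included; all
internal coordinates are Å with z the membrane normal.

## Worked example

```r
library(memmatch)

cfg <- synthetic_config(tilt_deg = 30, crossing_deg = 20,
                        bulk_pp_thickness = 31.6,         # DLPC-like P-P
                        bulk_hydrophobic_thickness = 20.0,
                        dent_amplitude = -4,              # local thinning
                        noise_sigma = 0.2, n_frames = 50, seed = 7)
gen <- generate_trajectory(cfg)

ts <- tilt_series(gen$traj, gen$topo, discard_fraction = 0.5)
map <- thickness_map(gen$traj, split_leaflets(gen$traj, "name P"),
                     discard_fraction = 0.5)
bulk <- bulk_thickness(map, protein_footprint(gen$traj))
hel <- helicity_series(subset_frames(gen$traj, 1:5), gen$topo)$fraction
```

This prints (via `sprintf` on the results above):

```
mean tilt: 30.0 deg, mean crossing: 19.9 deg
bulk P-P thickness: 31.60 A, min perturbation: -3.99 A
mean helicity: 0.90
```

The generator's parameters are recovered: tilt 30°, crossing 20°, bulk
thickness 31.6 Å, and the −4 Å dent appear in the measured series/maps;
the ideal helices assign ~90 % α-helical under mild thermal noise.

```r
mismatch_report(hydrophobic_length(29), 20.0)
#> <mm_mismatch> peptide 43.5 A vs membrane 20.0 A: +23.5 A (positive)
mismatch_report(hydrophobic_length(17), 35.7)
#> <mm_mismatch> peptide 25.5 A vs membrane 35.7 A: -10.2 A (negative)
```

A 29-residue leucine-rich helix in a thin (hydrophobic thickness 20 Å)
bilayer is +23.5 Å positively mismatched; a 17-residue helix in a thick
(35.7 Å) bilayer is −10.2 Å negatively mismatched.

## Command line

```sh
inst/cli/memmatch simulate  --config cfg.json --out traj.pdb --truth truth.json
inst/cli/memmatch tilt      --traj traj.pdb --discard-fraction 0.5 --out tilt.csv
inst/cli/memmatch helicity  --traj traj.pdb --out helicity.csv
inst/cli/memmatch thickness --traj traj.pdb --marker "name P" --spacing 3.3 \
                            --far-fraction 0.25 --out map.csv
inst/cli/memmatch assay     --table plate.csv --positive GpA:GpA \
                            --negative H2:H2 --alpha 0.05 --out results.csv
```

## Documentation

See the methods vignette (`vignettes/memmatch-methods.Rmd`) for the
models, parameter choices, what the synthetic generator does and does not
emulate, and known limitations.
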