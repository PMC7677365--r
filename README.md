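# helixcurate

Metadata-level curation for helical cryo-EM reconstructions of
filamentous assemblies (actin filaments and the like), plus the
atomic-model comparison metrics used to analyse the resulting
structures.

## Who this is for

Helical reconstruction boxes a filament into overlapping segments and
refines each as a single particle. Per-segment estimates (defocus,
Euler angles, origin shifts) are noisy, but the filament itself imposes
strong constraints: defocus varies smoothly along the tube, every
segment of one filament shares a polarity, and consecutive segments are
related by one helical screw step. This package is for people who want
to exploit those constraints between refinement rounds — repairing
defocus, flagging polarity flips, and selecting the segments whose
local helical geometry is self-consistent — without touching the image
data.

## What it computes

* **STAR I/O** — reads/writes RELION-dialect particle tables,
  preserving unknown columns verbatim (`read_particles`,
  `write_particles`).
* **Filament model** — groups segments into filaments, orders them
  along the principal axis of their coordinates, flags polarity flips
  against the circular-median psi, and windows filament traces into
  overlapping boxes: a 328-pixel box stepped by one 26-pixel subunit
  spans `floor(328/26) = 12` subunit steps (`group_filaments`,
  `check_polarity_consistency`, `window_filament`).
* **CTF smoothing** — for each particle, fits the mean defocus of the
  five consecutive segments centred on it after discarding the single
  highest and lowest values, and evaluates the least-squares line at
  the particle's own arc position; astigmatism `U - V` is preserved
  exactly (`trimmed_linefit`, `smooth_filament_ctf`, `smooth_ctf`).
* **Helical parameters** — per-step rise and twist from refined
  centres `p = coord * pixel_size - origin` and rot differences,

      rise_i  = (p_{i+1} - p_i) . u(psi),    u(0 deg) = (0, 1)
      twist_i = wrap(rot_{i+1} - rot_i)  in (-180, 180]

  then dataset mean/SD, removal of >2 SD outliers, and selection of
  steps inside the two-sided 95% band (`z = 1.959964`) recomputed on
  the survivors; a particle is kept only if all its valid steps are
  kept (`compute_steps`, `dataset_stats`, `select_particles`,
  `curate_particles`).
* **Structural metrics** — PDB/mmCIF reading with a PyMOL-style
  selection language, Kabsch superposition, selection RMSD,
  Shrake-Rupley SASA on a deterministic spiral lattice (960 dots,
  probe 1.4 A, Bondi radii), buried area, minimum group distances,
  percent B-factor differences, van der Waals clash scanning
  (overlap > 0.4 A), and side-chain rotation angles
  (`read_structure`, `kabsch_superpose`, `rmsd_selection`, `sasa`,
  `buried_area`, `min_group_distance`, `bfactor_group_percent_diff`,
  `clash_scan`, `sidechain_rotation`).
* **Synthetic data** — a seeded generator of filament metadata with
  known ground truth (rise 27.17 A, twist -166.7 deg, planted rise
  outliers, polarity flips and defocus spikes) and a toy helical
  polymer structure (`generate_dataset`, `generate_toy_polymer`).

## Worked example

```r
library(helixcurate)

cfg <- synthetic_config(seed = 7)       # 1000 particles, 20 filaments
sim <- generate_dataset(cfg)
res <- curate_particles(sim$set, expected_twist = -166.7)
res$report
#> <selection_report>
#> decision
#>                 keep      removed_outlier           removed_ci
#>                  664                  189                  128
#> removed_inconsistent
#>                   19
#> stage-2 stats: rise 27.178 +/- 0.716 A, twist -166.658 +/- 1.278 deg (n=841)
```

Reading the numbers: of 1000 synthetic segments, 19 touch no valid step
(polarity flips and their neighbours), 189 touch a step outside 2 SD in
rise or twist (the planted +10 A rise outliers plus the Gaussian tail
of the twist gate), and 128 more fall outside the recomputed 95% band.
The surviving 664 have per-step statistics centred on the generator's
truth (27.17 A, -166.7 deg); `write_particles(res$kept, "kept.star")`
emits them for the next refinement round.

A command-line front end covering conversion, smoothing, curation and
simulation is installed at `inst/scripts/helixcurate.R`:

```sh
Rscript inst/scripts/helixcurate.R curate --in particles.star \
    --out kept.star --sd-mult 2 --ci 0.95 --expected-twist -166.7
```

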