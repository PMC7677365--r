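---
title: "Curating helical cryo-EM particle metadata: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating helical cryo-EM particle metadata: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixcurate)
```

## The problem

Helical reconstruction treats overlapping boxed windows ("segments") of
a filament image as single particles. Because the filament is one
continuous physical object, several per-particle quantities estimated
independently by refinement software are strongly constrained:

* the local defocus must vary smoothly along the tube, because the ice
  and the specimen geometry vary smoothly;
* the in-plane angle psi of every segment of one filament must agree
  (up to noise), because it encodes the filament's polarity on the
  micrograph — a segment whose psi is off by ~180 degrees has been
  assigned the wrong polarity;
* consecutive segments must be related by (approximately) one helical
  screw step: an axial rise of ~27 Angstrom and a twist of ~-167
  degrees for an actin filament extracted at one-subunit spacing.

Refinement estimates violate these constraints for a minority of
segments because single segments have very low signal-to-noise. This
package exploits the constraints to *curate* the metadata: repair the
defocus estimates, flag polarity flips, and drop segments whose local
helical geometry is untrustworthy, so that a subsequent reconstruction
uses a cleaner, more homogeneous particle set.

The package operates purely on metadata (STAR tables) and atomic
models. It does no image processing.

## Segment windowing

A filament trace (polyline, pixels) is windowed into overlapping square
boxes translated along the arc by one subunit step. With a box of
`box_px` and step `step_px`, centers sit at arc positions
`box_px / 2 + k * step_px`, and a box spans
`floor(box_px / step_px)` whole subunit steps — 12 for a 328-pixel box
and a 26-pixel step. Centers whose box would leave the micrograph are
dropped. Arc length is piecewise-linear in the polyline, matching the
box-translation description of segment extraction.

A note on a symmetry subtlety: reversing the trace yields the mirrored
center set, which coincides with the forward set only when
`(L - box_px)` is a whole multiple of `step_px` (the center grid is
anchored at `box_px / 2` from the starting end). The tests exercise the
tiling case.

## Filament ordering and polarity

Segments are grouped by `(micrograph, helical tube id)` and ordered by
projection onto the principal axis of their coordinate cloud. The
principal axis — not psi — defines the order because psi is exactly the
quantity polarity flips corrupt. The axis sign is chosen so the
first-listed record projects lowest; exact ties break by `coord_x` then
`coord_y`, making the order fully deterministic.

Polarity consistency is judged against the *circular median* of the
filament's psi values (the data point minimising summed absolute
wrapped deviation). The median, unlike the circular mean, is unmoved by
a minority of 180-degree flips. A segment is flagged:

* `flip` when its psi deviates from the median by within `psi_tol` of
  180 degrees;
* `psi` when it deviates by more than `psi_tol` (default 15 degrees)
  without being a flip;
* `tilt` when `|tilt - 90| > 30` degrees — helical segments refine with
  tilt near 90, so a large excursion marks a misalignment even when psi
  looks fine.

The 15/30-degree defaults are this package's choices (field-typical
gates, generous relative to the ~1-degree angular noise of a good
refinement); published curation workflows report only the resulting
fraction of consistently aligned particles, not a rule, so the gates
are this package's own.

## Defocus smoothing

For each particle, the five consecutive filament positions centred on
it (clamped at the ends) provide five `(arc position, mean defocus)`
points. The single highest and single lowest defocus values are
discarded — a min/max trim that rejects up to two gross CTF-estimation
failures per window — and an ordinary least-squares line through the
remaining three is evaluated at the particle's own arc position.

Choices the procedure's description leaves open, resolved here:

* **Smoothed quantity.** The mean defocus `(U + V) / 2` is smoothed and
  the astigmatism `U - V` (and its angle) is preserved exactly, so the
  smoother cannot invent astigmatism changes.
* **Abscissa.** Arc position in Angstrom, not particle index. For
  evenly spaced segments the two are affinely equivalent and give
  identical fits; for unevenly spaced ones arc position extrapolates
  correctly.
* **Ends.** The terminal window is reused for the two particles at each
  filament end (an extrapolating fit). Filaments with fewer than five
  particles pass through unchanged.
* **Ties.** Tied extreme values remove the later-indexed point. Any
  fixed rule works; determinism is what matters.

## Rise and twist per step

For consecutive consistent particles `i, i+1`, the refined segment
centre is `p = coord * pixel_size - origin` (origin shifts are
*subtractive* in the dominant refinement dialect; `origin_sign` flips
this for the additive dialect). Then

* `rise = (p[i+1] - p[i]) . u(psi_mean) / n_subunit_steps`, with
  `u(psi)` the in-plane axis unit vector under the convention
  `u(0) = (0, 1)` rotating counter-clockwise, and `psi_mean` the
  circular mean of the pair's psis;
* `twist = wrap(rot[i+1] - rot[i])` into `(-180, 180]`, optionally
  re-wrapped to the branch nearest an expected twist (for actin,
  -166.7 degrees, where a wrap ambiguity with +193.3 would otherwise
  lurk).

The out-of-plane (tilt) contribution to rise is ignored: helical
refinement constrains tilt near 90 degrees and the tilt gate removes
violators, so the in-plane projection is accurate to second order in
the tilt deviation.

Dataset statistics are sample mean and standard deviation (n-1) over
valid steps; twist is averaged on the wrapped branch around its
circular mean, with an error if any step strays more than 90 degrees
from that mean (the branch would be ambiguous).

## Two-stage selection

Stage 1 removes valid steps with `|rise - mean| > 2 sd` **or**
`|twist - mean| > 2 sd`. Stage 2 recomputes the statistics on the
survivors and keeps steps within `mean +/- 1.959964 sd` on **both**
parameters (the 95% two-sided Gaussian band). The band is applied per
parameter, not elliptically, and stage 2 deliberately re-estimates the
statistics after the gross outliers are gone — "remove >2 SD outliers,
then keep a 95% confidence interval" admits either reading; the
sequential per-parameter reading is the simplest that uses both
numbers.

A particle is kept only if *every* valid step it participates in
survives; steps are edges between particles, and the conservative AND
keeps only particles whose local geometry is trustworthy on both sides.
Particles touching no valid step are `removed_inconsistent`.

Degenerate dispersion: an SD that is zero — or within double-precision
rounding of zero, `sqrt(eps) * max(1, |mean|)` — passes its gate
trivially. Without the rounding tolerance, a dataset with numerically
constant twist (SD ~1e-13 from wrap arithmetic) would absurdly fail a
fraction of steps on floating-point jitter.

## The synthetic world

`generate_dataset()` emulates the metadata regime of a filamentous
actin dataset: 26-pixel subunit steps at 1.045 Angstrom/pixel (hence a
true rise of 27.17 Angstrom), twist -166.7 degrees, 328-pixel boxes,
defocus around 1.5 micrometres varying linearly along each filament.
Filaments are straight lines at random orientations — curvature never
enters the curation math, and adjacent boxes of real filaments are
locally straight. Noise is i.i.d. Gaussian per particle (1 degree on
angles, 0.5 Angstrom per origin component by default); the generator's
job is controllable structure with exact ground truth, not image-level
realism. Planted defects:

* **rise outliers** (5% of particles by default): the step entering the
  particle carries a +10 Angstrom rise shift, propagated to all
  downstream positions, so exactly one step per outlier is wrong;
* **polarity flips** (2%): psi + 180 and negated rot;
* **defocus spikes** (2%): +5000 Angstrom on top of the smooth
  gradient.

What a green test establishes — and what it does not: recovery and
selection tests prove the estimators and gates are mathematically
correct against the generator's truth; they cannot prove anything about
image-level effects (CTF model error, correlated noise along a
filament, bent filaments), which the generator does not model.

One test-design consequence is worth stating plainly. When angular
noise is present, the 2 SD twist gate flags the expected ~5% Gaussian
tail of *clean* steps — that is the procedure behaving as designed, not
an error. The planted-outlier scoring test therefore plants its gross
defect purely in rise (angular noise off), where stage 1 isolates
exactly the planted steps and can be scored against the labels at the
binomial rate.

## Structural metrics

* **Superposition** is the SVD-based Kabsch solution with the
  determinant correction forcing a proper rotation. It is verified
  against a brute-force rotation-grid search (Fibonacci axis lattice x
  1-degree angle sweep, evaluated in closed form per axis).
* **SASA** is Shrake-Rupley with a deterministic Fibonacci spiral
  lattice (default 960 dots; isolated-sphere error < 0.5%), probe 1.4
  Angstrom, Bondi radii (C 1.7, N 1.55, O 1.52, S 1.8, P 1.8, H 1.2),
  all overridable. No randomness: results are exactly reproducible.
* **Buried area** of a group is its SASA alone minus its SASA in
  context, verified against the analytic spherical-cap area for two
  contacting spheres.
* **Clash scanning** reports heavy-atom cross pairs with van der Waals
  overlap above 0.4 Angstrom (a common strong-contact criterion; the
  source distinguishes strong from minor clashes only pictorially).
* **Side-chain rotation** uses best-fit ring-plane normals for aromatic
  residues (angle folded into [0, 90] degrees) and the CB-to-terminal-
  heavy-atom vector otherwise ([0, 180] degrees).
* **Selections** are conjunctive (`chain A and resi 373-375 and
  sidechain`); "side chain" means all non-backbone heavy atoms, with
  the backbone defined as N, CA, C, O, OXT — so the C-terminal carboxyl
  group is O + OXT + C.
* Altloc duplicates resolve to the highest-occupancy conformer at parse
  time.

The headline structural comparisons for pyrenyl-actin (Calpha RMSD
between the two deposited filament models, the +7.3% B-factor
difference over
residues 373-375, the ~0.1 Angstrom^2 SASA of the C374 side chain in a
filament, the ~11 Angstrom K113-to-C-terminus distance) all require the
deposited PDB entries. They are reproducible with these functions once
the files are downloaded, e.g.

```r
a <- read_structure("7k20.cif"); b <- read_structure("7k21.cif")
bfactor_group_percent_diff(a, b, "resi 373-375")
```

but are not part of the offline test suite. The toy polymer
(`generate_toy_polymer()`, a synthetic stand-in, never a substitute for
a deposition) exercises the same code paths with constructed answers.

## Known limitations

* Ordering by principal axis assumes filaments are not strongly curved
  within one tube's extent; a U-shaped trace would order incorrectly.
  Real helical picks are close to straight at this scale.
* The defocus smoother assumes at most two gross CTF failures per
  five-particle window; three or more in one window defeat the trim.
* The twist branch logic assumes the dataset's true twist is not near
  +/-180 degrees by more than the noise width, which holds for actin.
* `read_structure` parses coordinates, B-factors and occupancies only;
  anisotropic displacement, insertion codes and multi-model files are
  out of scope.
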