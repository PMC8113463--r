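---
title: "Measuring promoter spacer remodeling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring promoter spacer remodeling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spacergeom)
```

## The scientific problem

MerR-family transcription factors (EcmrR, BmrR, CueR) activate bacterial
promoters whose -35/-10 spacer is 19-20 bp instead of the consensus
17 +/- 1 bp. They do so by physically remodeling the spacer: sharply
kinking the DNA backbone, breaking the central base pair of their
pseudo-palindromic binding site, and globally under-twisting the duplex so
that the -35 and -10 elements move closer together and rotate back into
register for the sigma factor. Quantifying that remodeling from atomic
coordinates takes a small chain of structural measurements:

1. a **reference frame per base**, fitted in the standard (Tsukuba
   convention) way;
2. **Watson-Crick pair detection**, including recognizing the broken
   central pair;
3. **base-pair step parameters** (shift, slide, rise, tilt, roll, twist)
   and the **helical set** (h-twist, h-rise, displacements) in the CEHS
   mid-step-frame scheme;
4. spacer-level statistics: the **end-to-end spacer length** (centroid of
   the first pair to centroid of the last), the **kink angle** (deviation
   from collinearity among three block centroids, 6/7/6 for 19 bp and
   5/7/5 for 17 bp), and the **under-twist** (ideal B-form total twist
   minus the extrapolated measured total);
5. the **transcription bubble size** (longest bounded run of unpaired
   template-strand nucleotides);
6. between conformational states, **rigid-body domain motion** (Kabsch
   superposition on a fixed reference, then rotation angle and centroid
   displacement of the moving domain), and **buried surface area** at
   protein-protein contacts (two-sided delta-SASA by Shrake-Rupley).

Every stage is exercised against a deterministic synthetic B-DNA builder,
so the whole chain is testable without downloading coordinates.

## Base frames and pair detection

Each base frame is the least-squares rigid transform carrying an embedded
idealized base (standard reference frame coordinates; x toward the major
groove, y along the pairing edge toward the reference-strand sugar, z the
base normal) onto the observed ring atoms (9 for purines, 6 for
pyrimidines). The fit RMSD is reported; missing ring atoms are an error
naming the absentees. In this convention an ideal Watson-Crick partner's
frame is the reference frame with y and z negated, which gives clean
geometric pairing criteria. A pair is emitted when all of the following
hold (package defaults, all configurable):

| criterion | default | meaning |
|---|---|---|
| complementary identities | WC only | A:T or G:C; wobble and modified bases are skipped with a warning |
| donor-acceptor distances | all <= 3.5 Å | every canonical WC hydrogen-bond heavy-atom pair |
| base-normal angle | >= 140° | antiparallel stacking geometry |
| flipped origin distance | <= 2.5 Å | frame origins coincide after the partner flip |

The thresholds are the package's own choices of canonical literature
values; the criteria behind published statements of "base unpairing" are
typically unstated, so they are exposed in the configuration. A base
displaced 6 Å along the pair x-axis fails every criterion at once, which
is what the synthetic bubble generator uses.

## Step parameters and the under-twist statistic

For consecutive pair frames the CEHS construction takes the roll-tilt
hinge as the common normal of the two z-axes, rotates each frame half the
bending angle so the z-axes merge, measures twist between the y-axes about
the merged z, and expresses the origin difference in mid-step axes as
(shift, slide, rise). Roll and tilt are the projections of the bending
angle on the mid-frame y and x axes. The builder inverts this exactly
(`R1ᵀR2 = Rz(ω/2-φ) · Ry(Γ) · Rz(ω/2+φ)` with `Γ = sqrt(roll² + tilt²)`,
`φ = atan2(tilt, roll)`), which is what makes the builder-analyzer round
trip an exact oracle: scheduled parameters are recovered to < 0.1° / 0.01 Å
(in practice to ~1e-12) over 100 seeded random schedules per run.

The helical set comes from the full inter-frame rotation: **h-twist** is
its axis-angle rotation angle (oriented along the mid-step z; checked
against an eigen-decomposition oracle to 1e-6°), **h-rise** the
translation along that axis, and the displacements the perpendicular
offset of the frame origin from the screw axis. For a step with pure
twist, h-twist equals twist; a kinked step has h-twist >
twist, which matters below.

The spacer-level total twist follows the published convention: the mean
h-twist over measured steps is extrapolated over 19 base-pair steps
(`extrapolation_steps`, configurable), and the under-twist is the ideal
B-form total (36.0°/step, i.e. 10.0 bp/turn, configurable) minus that
total. Two notes on deliberately exposed choices:

* "extrapolate over 19 steps" is followed literally even though a 19-bp
  segment has 18 internal steps. When every step is measured, mean x 19
  and sum x (19/18) are algebraically identical; they differ only when
  steps are excluded, which is why `n_steps_used` is always reported.
* steps spanning an unpaired position are excluded from the mean by
  default: frames at broken pairs are unreliable, and a kinked step
  adjacent to the broken pair would otherwise inflate the mean h-twist
  (the h-twist of a step with a 76° roll spike is far above its twist).
  On a 19-bp spacer with the central pair broken this leaves 16 of 18
  steps.

## Spacer length, kink angle, and the centroid-policy choice

The spacer length is the Euclidean distance between the centroids of the
first and last base pairs; the kink angle partitions the spacer into
three blocks (central 7 bp, flanks split evenly), takes a centroid per
block, and reports 180° minus the interior angle at the central centroid,
so straight DNA reads 0°.

What "centroid" means matters more than it looks. The all-heavy-atom
residue centroid of a base pair does not lie on the helix axis: it
carries a radial offset (~1-3 Å, dominated by the backbone) whose
direction rotates with helical phase. Averaged over a 6-bp block
(216° of phase at 36°/step) the offsets do not cancel, and the three
block centroids of a perfectly straight duplex end up non-collinear: a
straight ideal duplex would read a kink of roughly 10°, and the spacer
length would change non-monotonically under small bends. Since a kink
statistic whose null value is not zero is not usable, `kink_angle()`
defaults to the `"frame"` centroid policy - block centroids of the
pair-frame origins, which lie on the helix axis by construction (for a
broken pair, the reference base's frame origin, which sits at the pair
midpoint in the standard convention). The `"all"` (residue-centroid) and
`"base"` (base-atoms-only) policies remain available for comparison with
centroid-based tools. The spacer length keeps the `"all"` default, since
its end-to-end character makes the offset a sub-Ångström effect and its
published tolerance (+/- 0.7 Å) absorbs atom-set differences.

A related geometric fact: for a bend concentrated at a single step, the
three-block centroid method reads *lower* than the underlying axis bend
(the central block centroid is pulled into the wedge; a raw 58° roll
spike reads ~43°). The published kink values are centroid-method
readings, so the generator provides `impose_centroid_kink()`, which
solves in closed form (root-find on the analytically composed step
rotations, before any measurement) for the roll spike whose
centroid-method kink equals the requested value - a 58° reading requires
a 76.05° spike. The raw `impose_kink()` records both the spike and the
analytic axis bend in its ground truth, and the axis bend is verified
independently by fitting axes through the terminal blocks' frame origins.

## The synthetic generator: what it emulates, and what it does not

`build_duplex()` composes the exact inverse of the analyzer's step
convention, placing idealized base pairs with zero intra-pair
deformation. Defaults are ideal B-form (36.0°/step, 3.38 Å rise, all
else zero) - the reference object the under-twist is measured against.
On top of that, schedules emulate the published study conditions:

* **remodeled 19-bp spacer**: uniform under-twist of 82° total
  (36 - 82/19 = 31.684°/step), a central kink calibrated to read 58°, and
  the central pair opened - the bound-regulator state. The open pair
  excludes the kinked steps from the h-twist mean, which is precisely why
  both 58° and 82° are recovered simultaneously;
* **bubble scaffolds**: 30-bp duplexes with 13 or 14 consecutive pairs
  opened (the open-complex and initial-transcribing bubble sizes; their
  difference is the 1-nt scrunching expansion);
* **two-state domain fixtures**: a rigid domain rotated 39° about a hinge
  with a 21 Å centroid displacement against a fixed reference, the
  published sigma-factor non-conserved-region motion between initiation
  and early elongation.

Deliberate limitations: the sugar-phosphate backbone is a rigid
decorative template attached in each base frame (plausible bond geometry,
but not re-puckered at kinked or unwound steps - only ring atoms are
geometrically exact, and all analysis frames fit ring atoms only);
intra-pair parameters (propeller, buckle, opening) are zero; there is no
sequence-dependent step-parameter statistics, solvent, or thermal noise.
Passing tests therefore demonstrate the *measurement chain* is correct,
not that real cryo-EM coordinates are free of the modeling issues
(alternate conformers, missing atoms, real backbone geometry) the reader
should still expect; those paths are exercised separately with
hand-written fixtures.

## Superposition, domain motion, and buried area

`kabsch_superpose()` is the standard SVD solution with the reflection
excluded by sign correction; it is cross-checked in the tests against an
independent reference implementation and against brute-force random
rotations. `domain_motion()` first superposes state 2 onto state 1 on the
reference selection's C-alpha atoms (residues matched by chain and author
number; unmatched residues dropped with a warning), then takes the Kabsch
rotation between the domain C-alpha sets; the rotation angle is
`arccos((trace(R) - 1) / 2)` and the centroid displacement is measured
after reference alignment. The reference selection is explicit because
published superpositions often leave it unstated; results for mobile
domains can shift by several degrees with the choice, which is why it is
a required argument rather than a guess.

SASA is Shrake-Rupley with a deterministic golden-spiral point set
(960 points/atom by default, probe 1.4 Å, Bondi-type radii embedded as
data, hydrogens excluded by default, unknown elements fall back to
1.70 Å with a warning). Buried area between two disjoint selections is
the two-sided difference `SASA(A) + SASA(B) - SASA(AB)` with all other
chains excluded; because burial conventions differ between tools, the
one-sided interface area (half the total) is reported alongside.
Numerical behavior worth knowing: the point set is fixed in the lab
frame, so areas are rotation-invariant only to the quadrature accuracy
(~0.2% at 960 points, <= 0.5% change from 960 to 3840 points); the
per-atom and two-sphere values are verified against closed-form
spherical-cap areas to 1%.

## Problem sizes and determinism

All tests and the acceptance script run on synthetic inputs sized for a
desk machine: 19-30 bp duplexes, 100 seeded 6-bp schedules for the
round-trip property, 50-point clouds with 10,000 random rotations for
the superposition bound, and 24-atom helix pairs for the interface
checks. Everything is seeded; `build_duplex()` is fully deterministic
(identical schedules give bit-identical coordinates), and the batch
runner writes no timestamps into data files, so re-running a manifest
reproduces byte-identical tables.

## Reproducing published values from deposited entries

The published headline numbers are measurements on deposited coordinate
entries, and this package never touches the network. To reproduce them,
download the entries into a local mirror directory and either call
`measure_mirrored_spacers()` with per-entry strand selections or list the
files in a YAML manifest for `run_manifest()`. Expect agreement within
the conventions' slack (atom sets behind published centroids and the
superposition reference are typically unstated): a few degrees on
angles, sub-Ångström on lengths, ~15% on buried areas.

## A worked synthetic example

```{r example}
sq <- paste(rep(c("A", "T", "G", "C"), 5)[1:19], collapse = "")
sch <- impose_unwinding(step_schedule(sq), 82)
sch <- impose_centroid_kink(sch, 10, 58)
duplex <- open_bubble(build_duplex(sch), 10)
spacer_report(duplex$model, "A", "B")
```
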