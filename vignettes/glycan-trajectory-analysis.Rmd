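---
title: "Analysing the conformational dynamics of branched N-glycans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing the conformational dynamics of branched N-glycans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycotraj)
```

## The scientific problem

Complex N-glycans are branched oligosaccharides attached to asparagine
residues of proteins.  Their terminal sialic acids (NeuAc) can be removed
enzymatically by neuraminidases, and this desialylation changes how the
glycan moves: which conformational families it visits, how flexible its
antennas are, and how much of the underlying protein surface it shadows.
`glycotraj` packages the trajectory analyses used to characterise this
behaviour — conformer clustering, conformational-state labelling and
transition counting, RMSF with block averaging, inter-block contact maps,
glycosidic torsion statistics, and the "umbrella" projection of antenna
tips onto an oriented plane — together with a synthetic trajectory
generator, so that the entire analysis chain is exercised and validated
without access to molecular-dynamics data.

## Block-level representation

All analyses operate at the level of monosaccharide *blocks*, not atoms:
conformational families, contact maps "between each block", the RMSF of a
galactose centre, and the projection of galactose positions are all
block-level quantities.  Accordingly, each block carries a small set of
named pseudo-atoms: a ring triangle (`O5` ring oxygen, `C1` anomeric
carbon, `C5` exocyclic anchor), a centre marker `CM` (the triangle
centroid, used wherever a "centre of mass" is needed), and one
attachment carbon/oxygen pair per outgoing linkage (`C6`/`O6` for a 1-6
linkage, and so on).  This is enough to define every glycosidic torsion:

* phi about the anomeric bond: child `O5`–`C1` against the bridging oxygen
  and attachment carbon of the parent;
* psi about the aglycone bond;
* omega about the exocyclic `C5`–`C6` bond, which exists exactly for
  1-6 and 2-6 linkages.

The torsion quadruples are stored as data on each linkage, so a different
convention is a topology edit rather than a code change.  Eight chain
variants are built by `build_chain()`: bi- and tri-antennary chains, with
and without core fucose, with and without terminal sialic acids
(`Ng-c2Sf` … `Ng-c3`).  `desialylate()` and `defucosylate()` are exact
topology edits: removing the NeuAc blocks of a built sialylated variant
yields a topology identical to building the matching non-sialylated
variant.

Two conventions had to be fixed where the chemistry literature leaves a
choice.  The sialic-acid linkage is taken as alpha2-6 (NeuAc on Gal):
omega torsions are measured for 2-6 linkages, which is only meaningful for
a 6-position attachment.  And the inner core is defined as GlcNAc1,
GlcNAc2 and Man3 only; the core fucose, although attached to GlcNAc1, is
not part of the trunk used for orientation.

## The synthetic trajectory generator

The generator emulates the statistical structure that glycan MD
trajectories exhibit, not their physics.  Each free torsion of each
linkage follows a mixture of angular modes; within a mode, angles are
wrapped-Gaussian around the mode location, and the mode path is a
first-order Markov chain at the stored-frame resolution whose stationary
distribution equals the mode weights.  Cartesian frames are produced by
forward kinematics over the topology tree with a fixed rigid-geometry
template, so bond lengths and angles are exactly constant across frames
and all conformational variability enters through the torsions.

The default presets encode the characteristic per-linkage statistics of
bi- and tri-antennary chains:

* inner-core linkages are stable and unimodal, and do not depend on the
  sialylation state;
* phi of Man4(a1-3)Man3 is bimodal at +90/+170 degrees, with weights
  0.35/0.65 for the sialylated bi-antennary chain inverting to 0.52/0.48
  after desialylation;
* psi of Man4p(a1-6)Man3 is bimodal at +70/+180 degrees with 79%/21%
  occupancy when sialylated (0.60/0.40 after desialylation, a modelling
  choice: only the fact of a shift is documented for this torsion);
* for tri-antennary chains, phi of GlcNAc5pp(b1-4)Man4p collapses from a
  bimodal +50/-165 mixture (weights 0.40/0.60, a modelling choice) to a
  single -165 mode on desialylation, and the a1-3 phi weights are taken
  as 0.80/0.20 shifting to 0.60/0.40.

Parameters the underlying statistics do not pin down were chosen once, on
realism grounds, and are documented here rather than revisited:

* **Within-mode width.**  Flexible multimodal torsions use a ~20 degree
  sd (`concentration = 8.2`), matching the broad basins such torsions
  display; stable unimodal torsions use a ~10 degree sd
  (`concentration = 33`), since a chain in which every linkage fluctuates
  by 20 degrees accumulates so much tip variance that antenna positions
  lose all spatial structure.
* **Switching correlation time.**  5 ns by default.  No dwell-time or
  autocorrelation information is available for the reference system; 5 ns
  at a 10 ps frame spacing gives conformational dwell times of hundreds of
  frames and transition counts of the order tens per 1.5 microseconds.
* **Rigid template.**  Ring triangle side 0.25 nm, C–O bridge bonds
  0.14 nm, attachment bonds 0.15 nm, near-tetrahedral bond angles; block
  centres along a linkage end up ~0.55 nm apart and the fully extended
  bi-antennary chain spans ~3.5 nm root-to-tip, the right scale for the
  0.5–1.4 nm radial distances that matter downstream.  Attachment
  torsions are fixed per substitution position (trans for the 4-linked
  backbone, +60 degrees for 6-attachments, …), which separates branches
  and makes the all-trans chain the maximally extended one.
* **Free preset means.**  Torsion means that the reference statistics do
  not state (e.g. omega of Man4p(a1-6)Man3 at -60 degrees, psi of
  Man4(a1-3)Man3 at +20 degrees) were chosen so that the bimodal torsions
  genuinely act as hinges: the +70 degree psi basin folds the alpha1-6
  antenna against the trunk while the +180 basin extends it.

Seeds are explicit everywhere; replica seeds derive as `seed +
replica_id`, so a replica set is reproducible and mutually independent.

What the generator does *not* emulate — solvent, energetics, excluded
volume, correlated motion between linkages — bounds what passing tests
show about real data: they validate the analysis machinery (measurement,
clustering, decomposition, projection, counting) on data with known
ground truth, not the biophysics of any particular glycan.

## Conformer clustering

`gromos_cluster()` implements neighbour-counting clustering on the matrix
of pairwise least-RMSD superposed distances (Kabsch superposition over all
pseudo-atoms; the pair RMSD is computed from explicit rotation residuals,
which is numerically exact for near-identical frames).  At each step the
unassigned frame with the most neighbours within the cutoff becomes a
cluster centre together with its neighbours.  Ties are broken towards the
lowest frame index, making the procedure fully deterministic; clusters are
reported by size descending.  Replicas are pooled before clustering, since
occupancy percentages refer to all simulations together.

Two cutoff policies are supported and neither is privileged: a fixed
cutoff (0.3 nm default in the pipeline configuration) and
`select_cutoff()`, the smallest value on a 0.05–1.0 nm grid (step
0.01 nm) whose five largest clusters cover at least 90% of the frames.

## Conformational states and transitions

The named families of the bi-antennary chain are defined verbally in the
literature — "broken wing" (alpha1-6 antenna along the trunk), "bird"
(perpendicular to the trunk), "back-folded" (behind the trunk) — without
quantitative boundaries.  `label_states()` makes them operational in the
oriented frame of the umbrella projection: with `r` the planar radial
distance of the alpha1-6 terminal galactose centre,

* `broken_wing`: `r <= 0.8` nm on the front half-plane (`y <= 0`);
* `back_folded`: `r <= 0.8` nm on the rear half-plane (`y > 0`);
* `bird`: `r > 0.8` nm with the antenna-to-trunk angle within 90 +/- 45
  degrees;
* `intermediate`: everything else.

The 0.8 nm threshold separates the reported near-trunk spot radii
(~0.5 nm) from the extended ones (~1.4 nm); the rear half-plane is the
package's reading of "behind the inner core", and both thresholds are
arguments.  `count_transitions()` counts crossings between two chosen
states per replica (never across replica boundaries); frames in other
states do not interrupt a dwell, and a debounce length discards visits
shorter than the given number of frames, which suppresses
classifier flicker at basin boundaries.

## RMSF and contact maps

`mean_structure()` computes the per-atom mean after superposing every
frame onto a progressively refined reference (two passes).  `rmsf()`
superposes all frames onto that mean (fit group: all pseudo-atoms by
default, inner-core-only or none as options) and reports, for each
antenna-terminal galactose centre, the global RMSF and the per-window
values of the 10 ns block-averaging scheme — three 500 ns replicas give
150 window values.  Windows are non-overlapping, aligned to replica
starts, with partial trailing windows dropped.  `compare_rmsf()` is a
two-sided Welch t-test between window sets (the unequal-variance form,
since window variances differ between chains) at alpha = 0.05.

`contact_map()` takes "smallest average distance between two blocks"
as the mean over frames of the per-frame minimum pseudo-atom distance —
the quantity that actually measures contact; the alternative reading
(minimum of the per-atom means) was rejected because averaging before the
minimum erases transient contacts.  `difference_map()` subtracts two maps
over the blocks they share, which may differ only by NeuAc blocks; with
the desialylated chain first, positive entries are block pairs whose
distance grew after sialic-acid removal.

## Torsion distributions

`angular_histogram()` bins angles circularly (default 5 degree bins: 72
bins resolve basins separated by 60 degrees and more, the closest
separation of interest).  `modal_decomposition()` finds modes by circular
watershed: local maxima of a lightly smoothed histogram seed basins whose
boundaries sit at the deepest minima between adjacent peaks; each basin's
occupancy fraction is its raw mass and its location the circular mean.
Peaks below 3% of the tallest peak are not counted as modes, which keeps
sampling noise in near-empty regions from fabricating basins while still
resolving a 5% minority mode.  Fixed boundaries can be supplied instead
when a prescribed partition is wanted.  `compare_distributions()` reports
the total-variation distance between two histograms plus per-mode
occupancy shifts with modes matched by nearest circular location.

## The umbrella projection

`orient_frame()` places each frame in a canonical pose by rigid motion
only: the root (Asn) centre at the origin; the inner-core direction —
GlcNAc1 centre to Man3 centre — along +z; then a rotation about z so that
the branch reference vector (Man4 centre minus Man4p centre) lies in the
+x half of the xz plane.  Axes are right-handed; this convention puts the
alpha1-3 branch on the +x side.  The transform is idempotent and
invariant to any rigid pre-motion of the input, and degenerate geometry
(zero-length trunk, branch vector parallel to z) raises an explicit
error rather than an arbitrary pose.

`project_antennas()` records the oriented (x, y) of each antenna's
terminal galactose centre — the area the antenna shadows on a
hypothetical protein surface under the glycan.  `occupancy_spots()` bins
these points (0.1 nm default), finds connected regions of bins above a
density floor (1% of frames), takes each region's points' mean position
as a spot centroid, and assigns every frame to the nearest centroid
within 0.4 nm — frames beyond that stay unassigned, forming the diffuse
"spread" fraction.  Spot occupancies are therefore assignment fractions,
not raw bin masses.  With the default presets the projected clouds are
broad: a spotless antenna is a legitimate outcome meaning the tip never
concentrates anywhere at the 1% floor, exactly as a widely spread antenna
should read.

`correlate_distance_dihedral()` relates the 3D distance between an
antenna tip and the inner-core centre (centroid of the GlcNAc1, GlcNAc2
and Man3 centres — chosen over the planar radial distance as the more
direct reading of "distance from the inner core") to any torsion series
by Spearman rank correlation, with average ranks on ties and a
large-sample normal p-value.  Because torsions are circular, the angle
series is first re-centred about its circular mean so that the +/-180
degree cut falls in a sparse region; without this, a basin straddling the
cut is split into the two extremes of the rank scale and the measured
association collapses.

## Numerical choices and degenerate inputs

* Angles are degrees in `(-180, 180]` everywhere; all operations are
  invariant under +/-360 degree shifts of their inputs.
* Torsion signs follow the standard right-hand convention (validated
  against an independent projection-basis formula and `bio3d`).
* Collinear torsion geometry, zero-length orientation vectors, empty
  trajectories, non-stochastic switching matrices, and atom-count drift
  in trajectory files all raise explicit errors.
* Clustering ties break to the lowest frame index; cluster numbering is
  by size descending with extraction order on ties.

## Problem sizes

The validation suite runs the statistical recovery checks at the full
protocol frame count (150,000 torsion samples, 10 seeds) where only a
scalar series is needed, and generates Cartesian trajectories at 1,000 to
5,000 frames per replica — ample for the geometric and bookkeeping
contracts being checked, since every such check is either exact or has
ground truth planted by the generator.  Clustering inside the pipeline is
performed on an even-stride subset (1,200 frames by default) because the
RMSD matrix grows quadratically; the stride is recorded in the cluster
summary.

## Known limitations

* The coarse block geometry is a kinematic scaffold, not a force field:
  no excluded volume, no solvent, no energetic coupling between torsions.
* The state classifier is a geometric operationalisation of verbal
  definitions; its thresholds (0.8 nm, 90 +/- 45 degrees, front/rear
  half-planes) are defensible but not unique, and are exposed as
  arguments.
* Transition counts depend on the debounce length when labels flicker at
  basin boundaries; counts are reported together with the debounce used.
* Published MD-derived magnitudes (conformer percentages, RMSF in the
  0.66–0.84 nm range, cluster counts of 20–38) require the original
  microsecond-scale ensembles and are not reproduced by the synthetic
  generator; the package reproduces the *methods* and validates them on
  planted ground truth.
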