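---
title: "Quantifying airway branching under negative transpulmonary pressure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying airway branching under negative transpulmonary pressure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(airwaymorph)
```

## The problem

During the pseudoglandular stage of lung development (around E12.5 in the
mouse), luminal fluid keeps the transpulmonary pressure — the difference
between the pressure in the airway lumen and the pressure of the fluid
surrounding the lung, `ΔP = P_lumen − P_reservoir` with
`P_reservoir = ρgh` for a hydrostatic head of height `h` — slightly
positive, and this distension is required for normal branching. Explant
culture systems can reverse the sign of `ΔP` by raising a medium column
above a trachea-occluded lung. Under increasingly negative `ΔP`,
branching slows, the neck of the right cranial (RCr) secondary bronchus
narrows, and terminal buds become cystic, while the basal epithelial
surface area and the lumen-inclusive volume keep growing linearly in
time, essentially independent of pressure. Relating the *allometric*
growth (fold-change in terminal branch number, `y`) to the *isometric*
growth (fold-change in basal surface area, `x`) gives a scaling law
`y = c·x^a`; explant trajectories at all pressures collapse onto a
single curve with exponent near `a = 1.67` and `R² ≈ 0.97`.

`airwaymorph` implements the complete quantitative side of such a study
on synthetic data: a seeded generator of ground-truth airway trees that
emulates the explant phenotypes, rasterization into binary
confocal-style volumes, 3D skeletonization with distance-transform
radius estimates, canonical lineage annotation (Tr, R, L, RCd, RAc, RMd,
RCr, L1–L5), whole-lung morphometry, the allometric analysis, and a
steady-state model of oxygen in the medium column. Because every volume
comes from a known tree, each stage of the image pipeline can be
validated against closed-form oracles.

## The synthetic airway generator

### Canonical topology

`build_canonical_tree()` constructs the stereotyped E12.5 tree: the
trachea (Tr) bifurcates into right (R) and left (L) primary bronchi; R
carries the caudal (RCd), accessory (RAc), medial (RMd) and cranial
(RCr) secondary branches, and L carries five secondary bronchi (L1–L5).
RCd/RAc (and L1–L3) attach laterally along their parent — domain
branching — in proximal-to-distal order; RMd/RCr (and L4/L5) are the
dichotomous bifurcation at the parent's distal end, the cranial-most
daughter named last. That gives 12 segments and 9 terminal branches at
t = 0.

Geometry is drawn per seed within fixed ranges: trachea radius 50 µm and
length 150–170 µm, primary bronchi radius 40 µm and length 230–260 µm,
secondaries radius 35 µm and length 140–165 µm, branch angles 35–70°.
The primaries sit at the long end of the plausible range because five
junction "blobs" of ~35 µm radius must stay separable along them — two
centerline junctions closer than roughly the local tube radius merge
into one in any skeletonization. Only fold-changes are analysed
downstream, so these lengths set scale and resolvability, not results.

### Growth schedules

`grow_tree()` evolves a t = 0 tree to time `t` under pressure `P`:

* **Isometric schedule.** Basal surface area follows
  `A(t) = A0·(1 + k·t)` with `k = 0.018` per hour (a 2.3-fold increase
  by 72 h), independent of pressure. After branch addition, all radii
  except RCr's are rescaled by a single factor so the closed-form area
  hits this target exactly; segments also elongate by 0.3 %/h. The
  magnitudes are the package's choice of a realistic explant growth
  rate; the *linearity* and *pressure-independence* are the modelled
  biology.
* **Allometric schedule.** The target terminal-branch count is
  `N(t) = round(9 · A_fold(t)^(a*·f(P)))` with `a* = 1.67` and a
  relative branching intensity `f(P)` interpolating 1.04/1.00/0.96 at
  −100/−400/−1000 Pa. An exactly pressure-independent area plus an
  exactly shared power law would force pressure-independent branch
  counts; the ±4 % tilt of the effective exponent is the smallest
  perturbation that makes branching decrease with pressure magnitude
  while keeping all pressures on one collapsed curve (pooled slope
  `a*` by symmetry, exponent spread 0.13, well under the 0.2 collapse
  threshold).
* **RCr schedule.** The RCr branch and its descendants narrow by
  `1 − (t/72)·s(P)` with `s` = 0.2/0.4/0.6 at the three anchor
  pressures, so after 72 h the −1000 Pa neck is exactly half the
  −100 Pa control. RCr is excluded from the area normalization so this
  ratio is not distorted.
* **Cystic tips.** Terminal bud tips widen by a factor 1.0/1.12/1.3 at
  the anchor pressures over their distal 40 %, ramped toward the tip.
  The widening is collision-aware: a bud expands only into available
  space.

Each addition targets a seeded choice of terminal branch and is lateral
or a tip bifurcation, 50/50 by a seeded draw. Lateral attachments are
spaced in physical units (neighbouring junction blobs scale with the
final radii) and are forbidden near the parent tip, where the residual
stub would be indistinguishable from a skeletonization spur. Growth-phase
geometry is computed on pressure-independent base radii, so trees grown
from one seed at different pressures share their branching geometry —
the paired-comparison design of the pressure sweep.

### Self-intersection and topology certification

Embryonic buds are short relative to their radii, so tubes near a
junction necessarily overlap ("webbing"); demanding contact-free
placement is geometrically infeasible. The generator therefore
distinguishes harmless from harmful contact: an overlap whose region is
contiguous with the parent solid leaves the union simply connected,
whereas contact separated from the parent creates a handle — a loop in
any topology-preserving skeleton. Candidate branches are
rejection-sampled (up to 50 directions, then alternative targets)
against this criterion, with two refinements: bifurcation daughters may
not both touch the same third branch (a three-body enclosure that
pairwise tests cannot see), and collision tests run at the radii
anticipated after area normalization (growth runs twice: the first pass
learns the normalization factor).

Because pairwise heuristics cannot *prove* the absence of handles, every
finished tree is certified directly: it is rasterized and the Euler
characteristic of the cubical complex is computed (`χ = V − E + F − C`;
a connected solid without cavities has `χ = 1 − handles`). Certification
runs at 2, 2.5 and 3.5 µm voxels, because near-contacts bridge at some
resolutions and not others. If certification fails, the seeded
construction replays with a derived sub-seed, so every seed yields a
valid tree deterministically.

## Rasterization

`rasterize()` voxelizes the union of tapered capsules — spheres of
linearly interpolated radius swept along each polyline — onto a grid of
(default) 2–2.5 µm isotropic voxels, which matches confocal-scale
sampling of these structures; anisotropic spacing is supported
throughout in physical units. The smallest tube radius must span at
least two voxels. Enclosed background pockets between webbed tubes
(rasterization artifacts) are filled before skeletonization, since
homotopic thinning would otherwise preserve a shell around them.

## Skeletonization

`skeletonize()` reduces the binary solid to its topological centerline:

1. the exact Euclidean distance transform of the foreground is computed
   in physical units (separable lower-envelope algorithm);
2. voxels are deleted in order of increasing distance; a voxel is
   deleted only if it is *simple* — its removal preserves the number of
   26-connected foreground and 6-connected background components in its
   3×3×3 neighbourhood — and endpoints (≤ 1 foreground neighbour) are
   preserved.

The result is a 1-voxel-wide, 26-connected centerline homotopic to the
solid, with a per-point radius equal to the distance-transform value
(minus half a voxel for the digitization bias of the background
boundary). The point set is organised into a graph: 26-adjacency
triangles (digitization artifacts of diagonal steps) are resolved by
dropping the long diagonal, tiny residual squares are broken, and any
larger cycle raises an error — volumes with genuine handles are out of
contract. Junction voxels (degree ≥ 3) cluster into junction nodes;
junction–junction runs shorter than the larger blob radius are absorbed
into one cluster, because two branch points inside a common blob are not
resolvable. `prune_spurs()` removes terminal twigs whose protrusion
beyond the junction blob is below `max(2 voxels, 0.5 × junction
radius)` — a bud poking out less than half the local tube radius is a
thinning artifact, not a branch — iterating to convergence.

## Lineage annotation

`assign_lineage()` starts from the root endpoint (topmost by default,
matching images with the trachea at the top) and assembles anatomical
branches by walking junctions: an outgoing segment within 30° of the
incoming direction continues the current branch (a lateral junction),
otherwise all outgoing segments are daughters (a bifurcation).
Directions are measured just beyond the junction blob, where the
centerline has settled onto the branch axis. The root branch is Tr; its
two daughters are R and L by the sign of the initial x-displacement;
R's daughters get RCd/RAc/RMd/RCr and L's get L1–L5 in attachment
order, daughters of the terminal bifurcation ordered cranial-most last;
deeper daughters of branch X are X.1, X.2, …. Extra daughters beyond
the canonical vocabulary are left unassigned with a warning.
`count_terminal_branches()` counts segments whose distal end is an
endpoint (the bud-tip definition of a branch), excluding a labelled
trachea; `branch_radius()` reads the neck radius as the mean skeleton
radius over the 10–60 % arclength window, which avoids both the
junction blob and the (possibly cystic) tip.

## Morphometry

`surface_area()` uses the co-area identity: the integral of the gradient
magnitude of a smoothed indicator equals, in the continuum, the area of
its 0.5-level isosurface. The mask is smoothed with a Gaussian of
σ = 1.0 voxel before the gradient; at σ = 0.5 the discrete estimator
retains a ~4 % staircase overshoot on capsules, while σ = 1.0 brings
capsules and spheres within ~1 % of closed forms — that accuracy, not
convention, fixed the default. `region_volume()` is the foreground
count times the voxel volume. `fold_change_series()` normalizes each
record against the explant's t = 0 baseline, and `analytic_metrics()`
provides the closed-form oracle (frustum side walls, hemispherical end
caps, and junction-overlap corrections that include the exact mean
exit-chord of fat daughters; the correction is approximate and
validated at the 3–5 % level against voxel measurements).

## Allometric analysis

`fit_power_law()` fits `log y = log c + a·log x` by OLS — the standard
allometry estimator, and the form under which the single-curve `R²` is
reported; a nonlinear fit on the original scale is available as a
sensitivity flag. Points from all explants, timepoints and pressures are
pooled unweighted. `bootstrap_ci()` gives a percentile CI from
case-resampling, with the expanded-percentile small-sample adjustment
(plain percentile intervals of an OLS slope undercover at n ≈ 12).
`collapse_test()` compares per-pressure fits: the maximum pairwise
exponent difference (pass below 0.2) plus an F test of pooled versus
per-pressure models.

## The oxygen model

At steady state, diffusion through the medium column obeys
`D·φ'' = 0`, so the concentration is linear in depth. The surface value
follows Henry's law, `φ(0) = P_O2/Kc` with
`P_O2 = F_O2·(P_ATM − P_H2O)`; the gradient follows the flux balance
`dφ/dx = −r/(D·A)`, where `r` is the *total* consumption rate of the
tissue and `A` the vessel bottom area; hence
`φ(x) = φ(0) − x·r/(D·A)`. (A flux written as `J = r·A` is
dimensionally inconsistent with that gradient; the implementation uses
the flux-balance form throughout.) Defaults are the culture conditions:
`Kc = 1/0.0031 mmHg·dL/ml`, `P_H2O = 47.067 mmHg`, `P_ATM = 760 mmHg`,
`F_O2 = 0.21`, `r = 0.023×10⁻⁵ ml O₂/min` (one lung),
`D = 2.76×10⁻⁵ cm²/s`, `A = 9.6 cm²` (one well of a 6-well plate).
Since the inputs mix unit systems, everything is converted to a coherent
cm–s system internally (an SI route exists purely as a dimensional
audit; the two agree to 10⁻⁹) and reported in ml O₂/dL.
`concentration_profile_fd()` solves the same boundary-value problem by
finite differences as an independent oracle, and `sweep_consumption()`
scans rate multipliers 1–40× and column heights 0–100 mm, reporting
where the profile crosses the 1 % O₂ equivalent — the per-well tissue
load (three or four explants, stage-dependent volume) is uncertain, and
the 40× sweep is what absorbs that uncertainty.

## The experiment pipeline

`run_experiment()` composes everything: per replicate it builds a
baseline tree, grows it at each pressure × timepoint (defaults
−100/−400/−1000 Pa × 24/48/72 h × 3 replicates), rasterizes, measures
through both the oracle and the image pipeline, computes fold-changes,
fits the pooled power law with bootstrap CI, runs the collapse test and
tabulates RCr radii. Per-replicate seeds derive from the global seed by
a counter scheme, so adding replicates never perturbs existing ones, and
all outputs regenerate bit-identically from config + seed.

Problem sizes: the default grid is measured at 2.5 µm voxels (volumes of
roughly 40–90 million voxels per explant, about ten minutes for the full
grid on one core), which the phantom suite shows is comfortably inside
the accuracy tolerances; the RCr pressure comparison follows its own
protocol at 2.0 µm. These are the package's default problem sizes;
`experiment_config(spacing_um = 2)` reproduces the finest setting
everywhere.

## What the synthetic data do and do not show

The generator reproduces the *statistical and morphological structure
the measurements assume*: tubular geometry with realistic radii, webbed
junctions, canonical lineage, linear isometric growth, power-law
allometric growth, pressure-graded branching, RCr narrowing, cystic
tips, and seeded biological variability in geometry. It does not emulate
photorealistic confocal imaging (no PSF blur, no staining noise, no
mesenchyme), self-contacting airways, or segmentation errors — volumes
enter the pipeline as clean binary masks. Passing tests therefore
validate the measurement pipeline (skeletonization, naming, morphometry,
scaling analysis) on geometry like that of cleared, well-segmented
explants; they cannot certify robustness to segmentation artifacts in
raw confocal data. Known limitations: junctions closer than the local
tube radius are unresolvable in principle; terminal tips retract by one
tip radius in any medial skeleton (neck windows avoid this); and the
allometric calibration interprets "number of branches" as terminal
branch number — the alternative (all segments) is exported alongside for
sensitivity checks.
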