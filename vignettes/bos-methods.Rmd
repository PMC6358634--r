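---
title: "Beam orientation selection for MLC-based robotic SABR: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beam orientation selection for MLC-based robotic SABR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific models inside `mlcbos`, the
parameters that matter, the choices made where the design was genuinely
open, and what the synthetic phantom can and cannot tell you about real
patients.

## The planning problem

A robotic SABR delivery system aims beams at the target from up to 110
non-coplanar nodes at a nominal source–axis distance (SAD) of 800 mm,
shaping each field with a multileaf collimator of 26 leaf pairs, each
3.85 mm wide (maximum field 115 × 100 mm at SAD). Using all nodes
maximises plan quality but makes delivery slow, since the robot must visit
every node. The package studies how few, and which, nodes suffice: an outer
evolutionary search over beam subsets, where each candidate subset is
scored by running a complete inverse plan.

## Phantom and structures

Real planning starts from a CT; here a synthetic voxel phantom stands in.
Structures are analytic solids (sphere, z-aligned cylinder, box, and
annular shells defined by signed distance to a reference solid), voxelised
by centre inclusion: a voxel belongs to a solid iff its centre is inside.
Overlap is resolved by unique integer priorities — each voxel carries
exactly one label, that of the highest-priority structure containing it;
the PTV has the highest priority and the body the lowest, and everything
outside the body is air and excluded from all objectives.

The default phantom is a cylindrical body (radius 120 mm, half-height
80 mm) with a 25 mm spherical PTV offset 40 mm from the axis, a cylindrical
organ at risk abutting the PTV surface, and three 10 mm annular shells
A1–A3 around the PTV. The shells are the practical device that forces dose
to fall off isotropically around the target — without them a small number
of beams concentrates the exit dose in a few directions. Voxels are 5 mm
isotropic, giving ≈ 58 000 in-body voxels; this resolution keeps a full
selection study on one CPU in the minutes range while leaving > 500 voxels
in the PTV.

Default objectives (for a 40 Gy prescription): PTV a = 100, bounds
[40, 44] Gy; OAR a = 2, max 20 Gy; shells a = 0.5 with maxima 40/28/20 Gy
stepping down with distance; body a = 0.05, max 16 Gy. The large PTV
weight reflects standard practice of prioritising coverage; the shell
maxima encode the desired dose gradient. These were fixed once when the
default phantom was designed, the way a planner would choose a template,
and all are overridable per run.

## Candidate nodes

The node workspace is emulated by a deterministic Fibonacci spiral over a
polar cap of 110° about the superior axis, excluding a posterior cone of
half-angle 30° that stands in for the couch. These angular extents are
configurable defaults, not measured values — the vendor's collision-free
node set is proprietary and only known pictorially. The `seed` rotates the
spiral azimuthally so distinct reproducible sets can be drawn; a minimum
pairwise separation (default 5°) is enforced and generation fails if the
request cannot honour it. Evenly spaced subsets (e.g. the 36-node preset
analogue) come from greedy farthest-point subsampling seeded with the
maximally separated pair, which provably cannot decrease the minimum
pairwise separation.

## Dose engine

The vendor dose module is replaced by a pencil kernel, chosen to be the
simplest model with the right qualitative physics:

$$D(r, z, \ell) = C\,(\mathrm{SAD}/r)^2\, e^{-\mu z}\,
  e^{-\ell^2/2\sigma(z)^2}, \qquad \sigma(z) = \sigma_0 + k z$$

with $r$ the source distance, $z$ the radiological depth along the bixel
ray (uniform-step ray marching against the body solid, step = half the
smallest voxel spacing), and $\ell$ the perpendicular offset from the ray.
Defaults $\mu = 0.005\,\mathrm{mm}^{-1}$, $\sigma_0 = 2$ mm, $k = 0.02$,
calibration 0.01 Gy per weight unit at 15 mm depth, are qualitatively
water-like for a 6 MV beam; they are package defaults, not measured beam
data. Dose is exactly linear in fluence by construction — in reality the
sum of bixel doses only approximates a large open field, which is a known
limitation of influence-matrix planning generally.

Each beam's fluence grid covers the beam's-eye-view bounding box of the
projected PTV voxel centres plus a 5 mm margin, snapped outward to whole
bixels of 7.7 × 5 mm (across-leaf × along-travel); one grid row drives two
adjacent leaf pairs, a literal reading of the bixel height being twice the
leaf width, so at most 13 rows are deliverable. Per bixel column, entries
below 0.015% of that column's maximum are dropped. The per-column (rather
than global) normalisation was chosen as the most literal reading of
thresholding "each component" of the influence data; the kernel is also
hard-truncated at 5σ laterally, which only removes entries already below
that threshold. Collimator rotation is fixed at 0°.

## Objective and fluence optimisation

The objective is the quadratic one-sided penalty
$F = \sum_i a_i([d_i^{min}-d_i]_+^2 + [d_i-d_i^{max}]_+^2)$, a convex,
continuously differentiable function of fluence; each voxel counts once,
with no volume normalisation per structure (sums are written per voxel).
Minimisation uses a projected L-BFGS scheme: direction from the two-loop
recursion (memory 10; curvature pairs with $s^\top y \le 10^{-12}$
discarded), update $w^{x+1} = [w^x - \alpha p^x]_+$. Because no relaxation
schedule is prescribed for $\alpha$, a backtracking Armijo search (start 1,
halve, $c = 10^{-4}$) was adopted so that descent is guaranteed — the
objective trace is non-increasing by construction. Coordinates pinned at
the bound with outward-pointing gradient take the raw gradient direction so
the projection keeps them fixed (a light-weight active-set treatment);
if a quasi-Newton step yields no sufficient decrease the memory is cleared
and a plain projected-gradient step is tried. Convergence is a fixed
iteration budget (40 for standalone plans, 20 inside selection, matching
the intended usage pattern) plus early exit when the projected gradient
vanishes or the relative change in $F$ stalls below `tol` twice with a
fresh memory. On random small instances the converged objective agrees
with an independent bound-constrained solver (`optim`'s L-BFGS-B) to
better than $10^{-6}$ relative — that solver is used as a cross-check in
the tests, never as the implementation.

The starting fluence is uniform, scaled so the mean PTV dose equals the
prescription; this puts the optimiser in the basin a clinical optimiser
starts from and makes inner plans fully deterministic.

## Sequencing and aperture-weight optimisation

Fluence maps are quantized to integer levels (default: per-beam aperture
cap + 2, balancing reconstruction fidelity against segment count) and
decomposed row-wise by levels: level $t$ opens the columns with value
$\ge t$; one unit-weight aperture is emitted per pass over the rows'
pending intervals and identical consecutive shapes merge. Uncapped, the
weighted aperture sum reconstructs the quantized map integer-exactly; when
the per-beam cap (default 5, 3 for simple targets) bites, the segments of
largest weight × area are kept and the result is flagged approximate.

"Direct aperture optimisation" is implemented by converting back to a
fluence problem: each aperture becomes a single dose column (the sum of
its open bixels' influence columns) and the same projected L-BFGS runs
over aperture weights. Shapes stay fixed; whether leaf positions should
also move is not decidable from the available description of the original
scheme, so weight-only optimisation was chosen and is stated here
explicitly. Apertures whose optimised weight falls below $10^{-6}$ of the
largest are pruned — this is the rule that lets beams drop out of a plan
entirely.

## Evolutionary beam selection

Defaults: population 20, generations 20, K = 15 from 110 candidates,
crossover ratio 0.4/0.6, per-gene mutation 0.05, inner budgets 20 + 20.
Two details needed reconciliation. First, parent choice: "the fittest
tenth" is combined, yet offspring come from "randomly selected pairs".
Implemented as: the parent pool is the fittest ⌈population/10⌉ individuals
(minimum two), and each offspring draws its two parents uniformly without
replacement from that pool — with population 20 this degenerates to the
single top-2 pair, and with population 100 it is genuinely random pairing.
Second, duplicate genes: a drawn gene colliding with one already placed is
redrawn once by the same rule and accepted on a second collision;
duplicates are collapsed to the unique beam set for planning, so fitness
can reflect fewer than K distinct beams. Replacement is generational, and
the reported optimum is the best individual seen in any generation, which
plays the role of elitism without preserving individuals. Inner plans are
deterministic given the genome, so fitness is memoised per unique beam
set within a run; importance factors are fixed within a run — adjusting
them means a new run.

## Metrics and the time model

The conformity index is the volume receiving the prescription divided by
the PTV volume; DVHs use 0.05 Gy bins. The delivery-time estimate is
additive — setup 5 min, 10 s traversal + 5 s imaging per node, 3 s
reshaping per aperture, beam-on at 800 MU/min — because the vendor's
algorithm is a black box of which only the component list is known. The
parameters were fixed once to plausible magnitudes; only orderings between
plans (full node set vs subset vs selected) are meaningful, never absolute
minutes.

## Study conditions and scale

The shipped study (`scripts/acceptance.R` and the end-to-end tests) runs
the default 5 mm phantom with 40 candidate nodes, selecting K = 10 with
population 10 over 10 generations and reduced inner budgets of 8 + 8
iterations — sizes chosen so the whole study runs in about a minute on one
CPU while preserving the structure of the full-scale problem (the clinical-
scale 110-node, 20 × 20 EA configuration remains the package default).
Statistical-stability repeats use a coarser 10 mm phantom with 20
candidates, K = 5, 6 generations and 3 + 3 inner iterations, 25 seeds.

## What the synthetic study does and does not show

The phantom study demonstrates the mechanics: the optimiser reaches
solver-verified minima, sequencing is exact when uncapped, selected
subsets beat random subsets of the same size, coverage and conformity are
clinically shaped, and delivery time falls as the node count drops. It
does not reproduce clinical DVHs or objective magnitudes: real anatomies
are heterogeneous and asymmetric, a vendor dose engine includes scatter
and heterogeneity physics the pencil kernel omits, and objective values
are only comparable under identical importance factors. Absolute treatment
times depend on proprietary robot kinematics. Known limitations, shared
with the approach the package models: sweep sequencing yields many small
segments (high MU), the MU total is not part of the objective, and leaf
shapes are frozen after sequencing.
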