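---
title: "Minima-hopping Monte Carlo over docking pose libraries: the model behind DockMC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minima-hopping Monte Carlo over docking pose libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

DockMC simulates a crowded box of rigid proteins over very long
timescales by restricting the dynamics to the minima of the
intermolecular energy landscape. In a crowded environment a protein is
essentially always in contact with neighbors; the high-energy monomeric
configurations between docked states are short-lived barriers. The
package therefore never integrates motion through space: a move takes a
whole molecule ("ligand") directly from one docking pose to another
docking pose on a neighboring molecule ("receptor"), with poses drawn
from a precomputed library.

Two layers make this work:

1. **Pairwise pose libraries.** For every ordered pair of protein types,
   a systematic rigid-body search scores every rotation and translation
   of the ligand relative to the receptor. The scoring grid is a
   step-function approximation of the Lennard-Jones potential: the
   receptor is rasterized with a thin attractive surface layer (+1, one
   cell thick) and a repulsive core (-rho, default rho = 9), the ligand
   with +1 on every occupied cell; the score of a placement is the grid
   overlap, computed for all translations at once by FFT correlation
   (zero-padded, so linear rather than circular). The defaults - grid
   step 3.5 A, repulsion 9, rotation interval 10 degrees, and the
   30,000 best poses kept per ordered pair - are the intermediate-
   resolution docking regime the method was developed in. Pose energies
   are the negated scores: docked states are negative-energy minima and
   the monomeric state is exactly zero.

2. **The Markov-state Monte Carlo engine.** Each simulation step gives
   every molecule one move attempt, in a fresh random permutation. An
   attempt selects a receptor uniformly among the ligand's *neighbors*
   (copies whose center lies within the two bounding radii plus a 50 A
   margin, minimum image), then a pose uniformly from the pair's
   library. Because the number of available receptors differs between
   the current and the proposed state, the Metropolis rule carries a
   move-count correction to preserve detailed balance:

   P(i -> j) = min{ 1, exp[-(E_j - E_i)/T] x N_i / N_j },

   where N_m is the neighbor count in state m and T is a temperature in
   docking-score units. A move is rejected outright if any C-alpha of
   the moved ligand comes within 8 A (minimum image) of any other
   copy's C-alpha - except the new receptor, whose contact is sanctioned
   by the pose itself. Energy bookkeeping is incremental: the new match
   energy is credited to ligand and new receptor, the old match debited
   from ligand and old receptor; a molecule's energy is the sum over all
   matches it participates in.

Time is attached to the chain afterwards: with a constant Arrhenius
prefactor shared by all transitions, each step corresponds to a fixed
physical duration. Calibrating the simulated diffusion coefficient of a
villin-sized protein against reference MD data (3.5 A^2/ns, which
overestimates experiment threefold, hence divided by 3) gives 20 ns per
step at the paper-scale operating point; `calibrateTime()` reproduces
this calculation for any system.

## What the engine assumes

* **Rigid bodies, short-range contacts only.** The only interaction is
  the docking score of the bonded pair; bystanders act through the
  neighbor counts and the collision check. No electrostatics, solvent,
  or flexibility.
* **One owned match per molecule.** Each molecule has at most one
  outgoing bond (the match it holds as ligand); incoming bonds persist
  until their owners move. Clusters arise as connected components of
  the resulting graph. This matches the bookkeeping that subtracts
  exactly one "old match" per move while letting aggregates of several
  molecules share receptors.
* **Crowding.** The minima-hopping picture needs neighbors within reach
  at all times; the method is not meant for dilute solutions, and the
  volume fractions studied (0.10-0.30) keep every copy connected to the
  move graph.

## Key parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| box | 500 | A | cubic periodic box edge |
| temperature | 100 | score units | Metropolis scaling factor; the melting point of the studied systems |
| neighborMargin | 50 | A | added to the two bounding radii in the neighbor rule; admits the first receptor shell |
| collisionCutoff | 8 | A | minimal CA-CA distance; 0 disables the check |
| step (grid) | 3.5 | A | docking raster resolution |
| rho | 9 | - | repulsive core magnitude |
| spacing | 10 | degrees | rotation-set covering radius |
| topK | 30000 | - | poses kept per ordered pair |
| msdReferenceStep | 100 | steps | MSD reference, after off-lattice relaxation |
| nsPerStep | 20 | ns | physical time per step (calibrated) |

The bounding radius (maximum center-to-atom distance, not the radius of
gyration) is used in the neighbor rule on purpose: it guarantees that no
stored pose can place a ligand beyond the neighborhood that proposed it.

## Design choices where the design was open

* **Rotation sampling.** The library uses Super-Fibonacci quaternion
  spirals, a deterministic low-discrepancy covering of SO(3). The set
  size is `ceiling(4 / mu(theta))` with `mu(theta) = (theta - sin
  theta)/pi` the Haar measure of a theta-ball; the constant was fixed
  once by direct measurement of the covering radius (the maximum gap
  stays below the nominal spacing from 90 down to 10 degrees). The
  nominal spacing is the contract; the generator is an implementation
  detail.
* **Equal-share rounding.** The total copy count is split equally by
  type, the remainder going to the first types in input order -
  deterministic and testable.
* **Initial overlaps.** Copies are jittered by up to half a lattice step
  with no collision check at placement; overlaps melt away during early
  MC steps, which is why the MSD reference is deferred to step 100.
  `planCopies()` errors only when the lattice step falls below the
  largest bounding *radius* (unresolvable overlap) and warns below the
  largest diameter, since the method's own operating points place
  copies on lattices comparable to the protein diameters.
* **N_j evaluation.** The reverse move count is evaluated with the
  ligand at its proposed position and every other copy unmoved. A
  proposal whose destination has no neighbors has no reverse move and
  is rejected.
* **Residence episodes.** An episode is a ligand-receptor *pair*: it
  survives re-docking onto the same receptor in a new pose and ends
  when the ligand accepts a different receptor. Episodes still open at
  the end of a run are right-censored - excluded from the mean and
  counted - because averaging censored lifetimes would bias the
  estimate downward.
* **Melting inflection.** The inflection is located on the
  shift-versus-log10(T) curve (the most direct mobility readout) as the
  midpoint of the steepest-rise segment, with exactly tied segments
  averaged; on a symmetric sigmoid sampled on a decade grid this is the
  exact center. Flat or non-increasing curves return NA with a
  low-confidence flag.
* **Diffusion fit window.** `diffusionCoefficient()` fits the
  through-origin slope over lags between 10% and 50% of the available
  range, avoiding the reference-step transient and the noisy terminal
  lags. Single-reference MSD estimates carry an irreducible statistical
  error (the displacement of a finite set of walkers), so quantitative
  work should average the estimator over several reference origins, as
  the test-suite and the acceptance script do.

## The synthetic-structure generator

`syntheticProtein()` grows a self-avoiding C-alpha walk with 3.8 A
virtual bonds, confined to a sphere of radius 3.3 N^(1/3) A with a soft
centripetal bias and local backtracking on dead ends, then adds 3
pseudo-side-chain atoms per residue at 1.6-2.6 A. This emulates what the
docking stage actually consumes from a real structure - compact shape,
realistic volume-per-residue, a C-alpha trace for collisions - and
nothing more. It does *not* emulate secondary structure, sequence-
specific surface complementarity, or real binding funnels; passing tests
on synthetic globules therefore validate the machinery (grids, FFT
equivalence, detailed balance, bookkeeping, observable estimators), not
the biological realism of any particular pose. The toy scenarios go
further and remove the docking stage entirely, fixing hand-built pose
libraries whose stationary distributions are known in closed form.

## Numerical choices

* FFT correlations are rounded to 6 decimals; with integer-valued grids
  (rho = 9) scores are exact integers and equal brute force exactly.
* Acceptance probabilities are evaluated on the log scale, so deep
  downhill moves cannot overflow `exp()`.
* Pose ties are broken by (rotation index, lexicographic translation),
  making the ranked library deterministic.
* The minimum-image convention maps each component to (-box/2, box/2],
  the boundary tie resolved to +box/2.
* Incremental energies are integers whenever scores are, so the
  bond-graph recomputation check is exact; the public `applyMove()`
  verifies it on every call.

## Problem sizes used by the bundled analyses

The acceptance script runs the whole pipeline on a three-protein
synthetic mixture sized like the small-protein set (36, 56 and 76
residues) in a 170 A box - the smallest box that keeps the neighbor
cutoff under half the box edge - with a 45-degree rotation set, 2,000
poses per pair, 250-step temperature scans and 600-step production runs
at five volume fractions. These sizes were chosen once as the package's
desk-scale operating point: large enough for every observable to be
measurable, small enough that the full suite runs on one CPU in
minutes. The paper-scale operating point (500 A box, 10-degree
rotations, 30,000 poses, 10,000 steps) is reachable with the same code
and configuration objects, at hours per run.

## Known limitations

* Scores of the simplified raster are not GRAMM scores; energy scales
  (and hence the absolute melting temperature of small synthetic
  systems) differ from the published full-scale systems, even though
  every mechanism and observable is the same.
* The surface/core encoding is mildly asymmetric under exchanging
  ligand and receptor roles; for molecules only a few cells across the
  best-score asymmetry can exceed the ~10% grid-quantization level.
* Pure-R inner loops cap practical system sizes at a few hundred copies
  and ~10^4 steps per run; the engine was profiled and its hot paths
  are allocation-free, but paper-scale runs are overnight jobs.
* No electrostatics, desolvation, flexibility, or membranes; kinetic MC
  with precomputed rate catalogs is out of scope.
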