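---
title: "Modeling multichannel inward-rectifier block in persistent atrial fibrillation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling multichannel inward-rectifier block in persistent atrial fibrillation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(atriablock)
```

This vignette is the package's own account of the science it implements:
the models, the parameters that matter, the numerical choices, what the
synthetic-data generators do and do not emulate, and the limitations a user
should know before trusting a number.

## The cell model

The membrane model is the Courtemanche–Ramirez–Nattel (CRN) human atrial
myocyte: 21 state variables (membrane potential, 15 Hodgkin–Huxley-type
gates, 5 intracellular/compartment concentrations), with all sarcolemmal
currents expressed per unit capacitance (pA/pF). We transcribed the CRN
equations in full — fast sodium current with Luo–Rudy kinetics, the two
inward rectifiers, transient outward and ultrarapid currents, the rapid and
slow delayed rectifiers, L-type calcium current, pumps, exchangers,
background currents and the two-compartment sarcoplasmic-reticulum calcium
subsystem with instantaneous buffering. The implementation is validated
behaviorally in the test suite: the published resting state is in flux
balance (|total current| < 0.01 pA/pF), RMP ≈ −81 mV, and the paced
APD~90~ lies in the 270–330 ms band that independent CRN transcriptions
report at 1 Hz.

Cholinergic activity is added through the Kneller formulation of the
acetylcholine-activated inward rectifier,

$$I_{KACh} = \frac{10}{1 + 9.13652/[\mathrm{ACh}]^{0.477811}}
\left(0.0517 + \frac{0.4516}{1+e^{(V_m+59.53)/17.18}}\right)(V_m-E_K),$$

with two conventions worth stating explicitly:

* **ACh units.** The dose factor takes ACh in µM (the convention of the
  Kneller source model), so the constitutively active I~KACh~ of persistent
  AF ("5 nM acetylcholine") enters as `ACh = 0.005`. This gives a dose
  factor of 0.086 — a small constitutive conductance, not full vagal
  activation. We considered and rejected nM and mM readings: nM would make
  the current 22× stronger (unphysiological for a constitutive current),
  and mM would make it negligible, leaving inward-rectifier block with
  almost no I~KACh~ component to act on.
* **E~K~** inside I~KACh~ is the instantaneous CRN Nernst potential from
  K~i~ and K~o~, not a fixed constant, for consistency with the rest of the
  current set. Both inward rectifiers therefore vanish identically at
  $V_m = E_K$, which the tests assert.

Persistent-AF electrical remodeling is a multiplicative conductance
profile — `af_remodeling()`: g~K1~ ×2.0, g~to~ ×0.5, g~Kur~ ×0.5,
g~CaL~ ×0.3, ACh 0.005 µM. Profiles compose multiplicatively and never
mutate their input.

## Numerics of the cell integrator

Gates advance by Rush–Larsen ($y \leftarrow y_\infty + (y-y_\infty)
e^{-\Delta t/\tau}$), which keeps every gate in [0, 1] by construction;
membrane potential and concentrations advance by forward Euler. The default
single-cell step is 0.005 ms; a convergence test shows halving it moves a
paced APD~90~ by < 1 ms. Smaller steps (0.001 ms) are available through the
`dt` argument everywhere.

Two throughput optimizations are part of the numerical definition of the
solver and are covered by equivalence tests:

* Voltage-dependent rates are pre-tabulated on a 0.05 mV grid over
  [−120, 80] mV with the Rush–Larsen factors baked in, and linearly
  interpolated. `use_tables = FALSE` evaluates every rate exactly; the two
  paths agree to < 0.5 ms in APD~90~.
* Nernst potentials are refreshed every 10 steps (they depend only on the
  slow concentration variables). The cadence is identical in the
  single-cell and tissue integrators, so an uncoupled (D = 0) sheet matches
  an isolated cell bit-for-bit — an invariant the tests check at 10⁻⁹ mV.

## Drug block and Hill fitting

Block is steady-state and kinetics-free: at concentration $C$,
$f = 1/(1+IC_{50}/C)$ of the current is removed by rescaling its maximal
conductance by $(1-f)$. Because block and remodeling are both scalar
multiplications they commute exactly. The shipped IC~50~ presets are the
simulation set (0.97 µM I~K1~, 1.0 µM I~KACh~, 2.5 µM I~Kr~) — the default
for all cell/tissue runs — and the patch-clamp fit set (1.3/1.2/2.5 µM),
kept separate because whole-cell fits and the values driving the
simulations differ slightly in the source literature.

`fit_hill()` fits the variable-slope form
$Y = 1/(1+10^{(LogIC_{50}-X)\,Slope})$ by Levenberg–Marquardt from six
starting points (three logIC50 values across the data range × both slope
signs), keeping the lowest-RSS fit; R² is $1-SS_{res}/SS_{tot}$ on the
response scale. Degenerate (constant-response) data are rejected rather
than fitted. With the generator's defaults (Gaussian noise, sd 0.05, 8
log-spaced concentrations spanning ±1.2 decades around 1 µM, 3 replicates)
the true IC~50~ is recovered within 25% in ≈ 94 of 100 seeds; a shallow
slope of −0.42 makes the IC~50~ intrinsically soft, so occasional 30–40%
misses are expected statistics, not fitter failures.

## Protocols and AP measurement

`measure_ap()` uses fixed conventions: activation is the sample of maximal
dV/dt within 10 ms of stimulus onset (earliest on ties); the per-beat RMP
is the sample immediately before the stimulus (robust when block
depolarizes the diastolic potential, unlike a trace minimum); APD~90~ runs
from activation to the first crossing of
$V_{peak} - 0.9\,(V_{peak}-RMP)$, with sub-sample linear interpolation.
On discrete traces these conventions carry up to half a sampling interval
of quantization, which the synthetic piecewise-linear AP tests make
explicit.

The titration protocol is an isolated-cell adaptation: pace the remodeled
cell at 1000 ms cycle length for 10 beats (quasi-steady: 10 more beats move
APD~90~ by < 2 ms), apply the block instantaneously, pace 5 further beats,
measure the last. Whole-atria simulations measure these quantities during fibrillation; the
isolated-cell protocol trades that context for determinism and
seconds-scale runtimes, and expectations are widened accordingly (see
*Limitations*).

## The 2D tissue model

The anatomical atria are replaced by a structured 2D monodomain sheet:

$$\frac{1}{S_v}\nabla\!\cdot\!(D\nabla V_m) =
C_m\frac{\partial V_m}{\partial t} + I_{ion} - I_{stim},$$

with Godunov splitting — a reaction substep (the cell model at every node)
followed by an explicit five-point diffusion substep with zero-flux
boundaries. Working per unit capacitance reconciles the mixed units of the
monodomain literature: the solver sees the single coefficient
$D_{eff}=D/(S_v C_m)$ in mm²/ms. Defaults: dx = 0.3 mm, S~v~ = 0.02,
dt = 0.02 ms, and D = 0.0034 calibrated once so that a planar wave in
unremodeled tissue conducts at ≈ 60 cm/s. The stencil groups neighbor sums
pairwise, so mirroring the grid and stimuli mirrors the solution
bit-for-bit, and the diffusion substep leaves the spatial mean of V~m~
unchanged to < 10⁻¹⁰ mV — both tested. CV obeys the reaction–diffusion
$\sqrt{D}$ law within 5% once the wavefront is resolved; we measure the
ratio at dx = 0.15 mm because at the 0.3 mm default the discrete lattice
slows the slower wave by ≈ 8%, a known explicit-FD artifact that the
refinement-consistency test (0.15 → 0.075 mm) quantifies.

**Arrhythmia induction.** The S1–S2 protocol is a 2D adaptation: planar S1
stimuli from one edge (sinus-driven excitation), then ectopic S2 beats at
130 ms cycle length from a node cluster (pulmonary-vein ectopy). In a
homogeneous isotropic sheet a compact focal S2 almost never breaks —
there is no substrate heterogeneity — so for re-entry studies the S2
cluster is a quadrant-sized patch whose edge falls across the S1
repolarization tail (the classic cross-field configuration); the free end
of the resulting wavefront curls into a spiral. Replicate variation comes
from the S2 coupling interval, never from random numbers.

**Desk-scale re-entry conditions.** A rotor needs its wavelength
(CV × APD) to fit the domain. The test suite uses a 72 × 72 sheet
(21.3 mm) with D = 0.00085 (planar CV ≈ 30 cm/s, in the range of diseased
atrial tissue) and S2 couplings of 90/100/110 ms. Under these conditions:
the remodeled sheet sustains re-entry for > 2 s at ≈ 12 Hz (matching the
dominant-frequency scale of fibrillating atria); the unremodeled sheet
extinguishes within 600 ms of the last stimulus under the same scan —
couplings 90–110 ms fall inside its refractory period, and 310/330 ms
capture but cannot re-enter because the ≈ 9 cm unremodeled wavelength
dwarfs the sheet; 50% dual I~K1~/I~KACh~ block applied to an established
rotor terminates it within 240–470 ms in all three timing replicates,
while 30% — or even 90% — I~Kr~-only block leaves the rotor statistics
indistinguishable from control. These are the directional claims the
package asserts; rotor counts and absolute termination times are
geometry-dependent and are not asserted.

## Electrograms

`compute_egm()` discretizes the large-volume-conductor integral with
central-difference transmembrane gradients, the analytic kernel gradient,
volume element $dx^2 \times$ 0.3 mm (the wall is treated as a monolayer),
and K = −0.0398. The forward model is linear in V~m~, null for uniform
fields, decays with electrode height, and matches a hand-evaluated dipole
kernel to 10⁻¹²; the solver can also accumulate the same sum online during
a run (tested equal to the snapshot path).

Conditioning follows the standard dominant-frequency chain — 40–250 Hz
band-pass, rectification, 20 Hz low-pass — with 4th-order Butterworth
filters applied forward–backward for zero phase (the corner frequencies are
the specification; the filter family and order are ours). The DF is the
argmax of a Hann-windowed, zero-padded FFT power spectrum within 2–20 Hz;
signals shorter than 2 s are rejected so the resolution stays ≤ 0.5 Hz.

Morphology classification is threshold-based, since the original
definitions ("two negative or positive deflections", more than two =
fractionated) were applied visually: activation windows are segmented from
the conditioned envelope (peaks ≥ 30% of maximum); within a window, a
deflection is a signed excursion of the lightly smoothed raw signal beyond
20% of the window's maximal deviation from baseline (median), with
excursions closer than 10 ms merged. All three thresholds are arguments.
One deflection → single, two → double, more → fractionated; windows with
no deflection above threshold are reported unclassified rather than
guessed.

## Pore occlusion

The voxel-probe module answers: can a sphere of radius $r$ travel from the
extracellular to the intracellular side of a channel past a docked ligand?
The structure is voxelated at 0.2 Å; a voxel is van-der-Waals-occupied iff
its center lies inside any atom sphere (Bondi-style radii, hydrogen
1.2 Å). Feasibility of a probe position is evaluated in continuous
distance — voxel center to atom center ≥ atom radius + probe radius —
which avoids compounding two discretizations; the fully voxelized variant
(thresholding the Euclidean distance transform of the occupancy) is
available as `method = "edt"`, and the two agree on the blocking radius to
within one voxel on every test geometry. The verdict is an exhaustive
flood fill (26-connectivity by default, 6 selectable) from a 2 Å entry
slab at the grid top to the exit slab at the bottom, so every lateral
repositioning of the probe is explored; a greedy axial march would be a
subset of this search. An entry slab with no feasible position is reported
distinctly as "no aperture". Scans over the 1.4–3.9 Å ladder are monotone
by construction because the feasible sets are nested in $r$, and every scan
is repeated ligand-free so ligand-caused occlusion is separated from the
channel's intrinsic constriction.

Grid padding defaults to (largest vdW radius + largest probe) on all
sides, which guarantees the entry slab is open. The synthetic
membrane-slab fixtures instead use `pad_xy = 0.1` so the slab reaches the
lateral grid boundary — the sheet stands in for an infinite membrane, and
without it any finite atom set could be circumnavigated.

## Synthetic data: what it does and does not emulate

All generators are bit-deterministic under (parameters, seed).

* `gen_conc_response()` — Hill curve plus truncated Gaussian noise. Real
  concentration–response data have heteroscedastic, occasionally
  correlated errors; passing recovery tests here shows the fitter works,
  not that real chloroquine data are this clean.
* `gen_pore_geometry()` — a slab of 1.7 Å pseudo-atoms with an exact-radius
  ring stack, so the minimal free aperture is known analytically (ring
  radius − 1.7 Å, to within ≈ 0.05 Å of ring/layer discretization). The
  optional spherical pseudo-ligand of radius (aperture − gap) parked
  against the wall leaves a crescent whose largest inscribed sphere has
  radius exactly `ligand_gap`. This is deliberately not a Kir channel: it
  validates the probe arithmetic, not channel biology.
* `gen_egm_morphology()` — monophasic ~2 ms Gaussian deflections (1, 2, or
  k ≥ 3 per cycle) with timing jitter and additive noise. Clinical EGMs
  have far more baseline wander and far-field contamination.
* `gen_tissue_fixture()` — ready-to-run planar-wave and re-entry-seed
  scenarios with an S2 coupling scan.

## Problem sizes

The defaults used by the test and acceptance runs were chosen as the
smallest sizes at which each claim is physically meaningful: single-cell
protocols use 10 + 5 beats at dt = 0.005 ms; tissue runs use 72 × 72 nodes
at dt = 0.02 ms with 2.1 s of activity for sustainment and 1.2 s windows
for drug response; probe scans use the full 0.2 Å / 26-radius ladder on
~2 000-atom geometries, with compact ≤ 40³ grids for the brute-force
oracle comparisons.

## Known limitations

* **Absolute APD~90~ under constitutive I~KACh~.** Our drug-free remodeled
  baseline is 71 ms at 1 Hz (and 138 ms without ACh, the canonical value
  for AF-remodeled CRN). Whole-atria studies that report ≈ 98 ms use
  regional left-atrial cell variants whose conductance sets are not
  published; with the µM reading of the Kneller dose factor fixed by the
  source convention, we do not attempt to recover their absolute values.
  Relative drug effects are robust to this: dual block prolongs APD~90~ by
  +69% at 1 µM and +172% (triple) at 2.5 µM, and the monotone orderings
  (single < dual < triple; increasing with concentration) all hold. One
  ordering does not: in our cell, blocking I~KACh~ prolongs the AP slightly
  more than blocking the doubled I~K1~, because the Kneller current at
  µM-convention strength carries more plateau-range outward current than
  rectified I~K1~; studies with weaker constitutive I~KACh~ report the
  opposite pair order.
* The 2D sheet has no anatomy, fiber anisotropy (available but defaulted
  off), regional heterogeneity, or fibrosis; rotor life-times and
  termination times are therefore directional results only.
* Block is steady-state: no use-dependence, no voltage-dependent unbinding,
  no I~Na~/I~CaL~/I~Ks~ partial block.
* The pore module evaluates rigid geometry: no side-chain flexibility, no
  solvation energetics — a ligand that "blocks" here blocks a frozen
  structure.
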