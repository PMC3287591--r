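---
title: "Estimating single-channel water permeabilities from equilibrium trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating single-channel water permeabilities from equilibrium trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

aquaperm estimates the two single-channel water permeability constants of a
membrane channel — the osmotic constant $p_f$ and the diffusive constant
$p_d$ — from an equilibrium trajectory, together with the descriptive
quantities usually reported alongside them: channel occupancy, pore radius
profiles, water dipole order parameters and basic structural metrics. This
vignette explains the models, the tunable parameters, the synthetic data the
estimators are validated on, and the numerical choices the implementation
makes.

## The two permeabilities

Both constants have units of volume per time (cm$^3$ s$^{-1}$) and relate a
flux to a concentration difference: $p_f$ governs the net volume flux driven
by an osmotic gradient, $p_d$ the tracer flux driven by an isotopic labeling
gradient. Both can be extracted from an *equilibrium* simulation, without
applying a gradient.

**Diffusive permeability by event counting.** A permeation event is one
water molecule entering the channel's constriction region (CR) through one
axial boundary and leaving through the opposite one. With $N_\pm$ completed
bidirectional events pooled over $n_m$ channels during $t_{sim}$,

$$k_0 = \frac{N_\pm}{2\,n_m\,t_{sim}}, \qquad p_d = v_w\,k_0,$$

where $v_w = V_w/N_A \approx 2.99\times10^{-23}$ cm$^3$ is the volume of one
water molecule. `detect_events()` implements the counting with a per-water,
per-monomer three-state machine (outside below / inside, with entry side /
outside above). Only full boundary-to-boundary traversals count: waters that
back out the side they entered, waters that leave the CR laterally, and
waters already inside at the first analyzed frame contribute nothing.

**Osmotic permeability by collective diffusion.** The collective coordinate
$n(t)$ accumulates, frame pair by frame pair, the axial displacements
$dz_i$ of the CR waters in units of the channel length $\bar L$:
$dn = \sum_i dz_i / \bar L$, $n(0)=0$. At equilibrium $n(t)$ performs an
unbiased random walk whose diffusion constant $D_n$ — obtained from the
multi-origin mean-square displacement $\langle n^2(\tau)\rangle = 2 D_n
\tau$ — gives

$$p_f = v_w\,D_n.$$

An increment of one in $n$ corresponds to the net conduction of one water
through the channel.

**Single-fileness.** For strictly single-file transport of $N$ waters the
continuous-time random-walk (CTRW) picture predicts $p_f/p_d = N+1$: a
conducted water must make $N+1$ concerted steps to traverse, so tracer
transport is $N+1$-fold slower than collective transport. Water–water
interchange raises $p_d$ while leaving $p_f$ untouched and pulls the ratio
toward 1, the independent-particle value. The ratio is therefore a
dimensionless measure of how strictly single-file the channel is.

## Channel geometry

A channel is defined per monomer by two boundary atoms (single-atom
selections, e.g. backbone carbonyl oxygens at the CR ends), a channel axis
(by default the membrane normal, i.e. the z axis of the cell), and a lateral
cutoff. Per frame, the CR is the half-open axial interval
$[z_{bottom}, z_{top})$ spanned by the instantaneous boundary-atom
positions; a water oxygen is inside when its axial coordinate falls in the
interval and its radial distance from the axis is at most the cutoff. A
fixed axial window (`fixed_z`) can replace the instantaneous interval to
reproduce fixed-window occupancy or radius-profile conventions; both
conventions appear in the literature and differ mainly in how boundary
fluctuations are attributed.

Parameter defaults, with reasoning:

* `lateral_cutoff = 8` Å — generous versus a ~2 Å pore radius yet far below
  the ~25 Å spacing of neighbouring monomers in a tetramer, so it tolerates
  axis-anchor error without capturing a neighbour's waters. Waters eligible
  for several monomers go to the nearest axis.
* Half-open interval $[z_{bottom}, z_{top})$ — a water sitting exactly on a
  boundary belongs to exactly one side, so no crossing is double-counted.
* $\bar L$ is the time-averaged Euclidean boundary-atom distance, frozen per
  analysis run; the aggregate row is the mean and sample SD over monomers.

## Collective-coordinate bookkeeping

Which waters contribute $dz_i$ for a frame pair is a genuine design choice.
The package default is the **clipped, either-endpoint** rule: every water
inside the CR at either end of the frame pair contributes, with both
endpoint positions clipped to the CR interval. Under this rule a conducted
water contributes exactly $\bar L$ of displacement over its traversal, no
matter how the crossing falls relative to frame boundaries, so the
displacement budget is conserved and $D_n$ is unbiased for hopping-like
dynamics. The alternative **both-frames** rule (only waters inside at both
endpoints contribute, unclipped) discards the boundary-crossing steps; for a
single file of $N$ waters advancing by discrete hops this silently drops
$1/N$ of the transport per conduction and biases $D_n$ low by
$((N-1)/N)^2$ — about 26% at $N=7$. Both rules are implemented
(`contribution =` `"clipped"` or `"both_frames"`); the clipped rule is the
default for the reason above.

MSD estimation uses non-overlapping time origins by default
(`origin_stride = window_length`, 100 ps windows), which makes the origins
nearly independent; overlapping origins are available via a smaller stride.
$D_n$ comes from a free-intercept least-squares fit of
$\langle n^2\rangle$ versus lag over 10–100 ps. The free intercept and the
10 ps lower edge absorb the fast, anticorrelated onset that short-time water
motion produces; for pure hopping dynamics the MSD is linear from zero and
the choice is neutral. A negative fitted slope (possible in noise-dominated
data) is clamped to zero with a warning.

## Occupancy and water orientation

Occupancy histograms simply count CR waters per frame; the aggregate is the
mean and sample SD of the per-monomer means.

Water orientation is summarized by the Legendre order parameters
$P_1(z) = \langle\cos\theta\rangle$ and
$P_2(z) = \langle(3\cos^2\theta - 1)/2\rangle$, where $\theta$ is the angle
between the water dipole and the channel axis and $z$ is the oxygen's axial
position binned at 1 Å (bin width configurable; profiles are reported
relative to the channel midpoint so monomers align). $P_1$ ranges over
$[-1,1]$ and signs the mean dipole direction; $P_2$ ranges over $[-0.5,1]$
and distinguishes axial alignment ($P_2>0$) from perpendicular alignment
($P_2<0$). The dipole is the geometric HOH bisector by default; supplying
per-atom charges switches to the charge-weighted molecular dipole (for
rigid three-site waters the directions coincide). Per-bin averages pool all
frames and waters; the error bar is the SD of per-frame bin means. Empty
bins are reported as missing, never as zero. The hallmark of an aquaporin,
a bipolar dipole field that inverts at the NPA constriction, appears as a
sign change of $P_1$ and a minimum of $P_2$ at the inversion plane.

## Pore radius

The HOLE-style radius at an axial station is the radius of the largest
sphere centered in the perpendicular plane that touches no atom's van der
Waals sphere: maximize $f(c) = \min_i(|c - x_i| - R_i)$ over in-plane
centers $c$. The optimizer is a deterministic multi-start compass (pattern)
search — start points are the previous station's center plus a small ring,
step halving from 1 Å to 5 mÅ — rather than simulated annealing: pore cross
sections are close to convex, and determinism given the inputs is worth
more here than global-search robustness. Stations march along the axis at
0.5 Å (configurable), each seeded from the previous center; a station whose
best clearance is negative is occluded and reported as radius 0 with a
flag. Radii come from the Bondi table by default and can be overridden
per-atom (HOLE's own radius set differs; absolute radii shift by
~0.1–0.2 Å between sets, so cross-package comparisons of absolute radii
are qualitative). Waters and other non-wall atoms should be excluded via
the `protein_atoms` selection.

## Structural metrics

RMSD series, per-atom RMSF and window-averaged structures all build on a
proper (det = +1) Kabsch superposition. RMSD superposes each frame on the
reference by default, since monomer-level RMSD is otherwise dominated by
whole-tetramer drift. RMSF superposes each frame onto the mean structure
with one refinement pass (superpose, re-mean, superpose) before measuring
per-atom deviations; superposition is per selection, so passing one
monomer's atoms gives per-monomer RMSF.

## The synthetic single-file channel

`simulate_single_file()` generates trajectories with *known* transport
parameters so every estimator can be validated end to end without an MD
engine. The kinetics are the concerted CTRW of a single-file column:

* the whole file of `n_sites` waters shifts one site up or down at rate
  $K = \mathrm{hop\_rate}/n_{sites}$ per direction (the collective mobility
  of a file scales inversely with its size); the leading water leaves to a
  reservoir and a reservoir water enters the trailing site;
* every adjacent pair, including the two channel-mouth pairs (boundary
  water with a reservoir water), exchanges identities at rate
  $\mathrm{hop\_rate}\times\mathrm{interchange\_prob}$. An interchange moves
  two waters by equal and opposite amounts, so it changes $p_d$ but not
  $p_f$ — exactly the mechanism that degrades single-fileness.

This gives closed-form ground truth: $D_n = K$,
$k_0 = (K + \mathrm{hop\_rate}\cdot p)/(N+1)$, and

$$\frac{p_f}{p_d} = \frac{N+1}{1 + p\,N},$$

which is $N+1$ for strict exclusion ($p=0$) and exactly 1 for free
interchange ($p=1$). The event-driven (Gillespie) kinetics are exact and
subsampled onto the frame grid, so frame aliasing is a test dimension, not
a modeling error; reservoir pools are FIFO and rebalanced by recycling the
longest-parked water, which keeps entry sides unambiguous at frame
resolution.

Defaults emulate the conditions reported for archaeal aquaporin tetramer
simulations: `n_sites = 7` (channel occupancy ≈ 7 waters),
`site_spacing = 2.8` Å (a water–water hydrogen bond, giving
$\bar L \approx 19.6$ Å), `frame_interval = 2` ps (the usual snapshot
spacing), and `hop_rate = 25` ns$^{-1}$, chosen so that
$k_0 = \mathrm{hop\_rate}/(N(N+1)) \approx 0.45$ ns$^{-1}$ — the scale
reported for aquaporin channels. Waters are embedded in 3D with 0.3 Å
transverse jitter and hydrogens realizing a bipolar dipole field (dipole
rotating from $+z$ below the midplane through perpendicular at the midplane
to $-z$ above), so the orientation stage sees the qualitative aquaporin
signature.

What the generator deliberately does **not** emulate: occupancy
fluctuations (the file stays intact, so occupancy is constant at
`n_sites`), water–protein energetics, axis bending, and lateral escape
paths. Passing tests therefore demonstrate estimator correctness under the
transport model's assumptions, not robustness to every feature of real MD
data; the boundary-atom, lateral-cutoff and burn-in machinery exists
precisely because real trajectories are messier.

Geometric fixtures complete the validation: `make_cylinder_pore()` builds
stacked-ring pores with analytic radius (`ring_radius - vdw`, optionally
tapering), and `make_oriented_waters()` builds water sets with prescribed
dipole fields (aligned, perpendicular, isotropic, bipolar) whose order
parameters are known exactly.

## Problem sizes and reproducibility

The validation suite runs at desk scale: the CTRW recovery check uses four
channels of 100 ns each (2 ps frames), where the $p_f/p_d$ estimator's
sampling error is a few percent against the 25% acceptance band; estimator
unit checks use 20 ns series with 200 non-overlapping 100 ps windows;
geometric oracles use hundreds to $10^5$ waters. All stochastic stages take
a mandatory seed, echo it in their outputs, and identical seeds reproduce
byte-identical trajectories.

## Known limitations

* Event detection is frame-based: crossings faster than the frame interval
  in real (non-synthetic) data would be missed. `max_gap` warns on
  irregular sampling but cannot recover unseen crossings.
* The analysis assumes an orthorhombic, wrap-free trajectory; periodic
  unwrapping is the caller's responsibility.
* DCD reading is not implemented; PDB (multi-MODEL) and multi-frame XYZ are
  the supported interchange formats.
* Absolute pore radii depend on the van der Waals radius set; only
  radius *differences* along a profile are set-independent.
* The CR z-interval convention (instantaneous boundary atoms versus a fixed
  window) changes occupancy and profile axes slightly; both are offered and
  results state which was used.
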