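---
title: "Hard rods in shallow chambers: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hard rods in shallow chambers: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The physical problem

Colloidal liquid crystals built from long rod-like particles (virus
particles, cytoskeletal filaments, nanotubes) enter a regime that molecular
mesogens never reach: the particle length becomes comparable to the size of
the confining volume. `confinedrods` simulates this regime directly — hard
spherocylinders of length $L$ and diameter $D$ (all lengths in units of
$D$) between two plates a distance $H < L$ apart, laterally bounded by a
circular wall of radius $R_\mathrm{outer}$, optionally with an inner post of
radius $R_\mathrm{inner}$ that changes the topology from a disk
($\chi = 1$) to an annulus ($\chi = 0$). The lateral confinement strength
is $\kappa = L / 2R_\mathrm{outer}$.

Because the particles are hard, the only physics is entropy: excluded
volume drives nematic order (Onsager), the walls favour planar (tangential)
alignment, and the topology forces orientational singularities on the disk
(total tangential boundary charge $+1$) while allowing a defect-free state
on the annulus. The interesting behaviour is where these constraints
compete at the particle scale: bipolar states whose two $+1/2$ defects sit
inside, at, or (virtually) outside the disk ($B_i$, $B_b$, $B_o$,
$B_\infty$), and $n$-fold domain patterns $D_n$ on the annulus whose
symmetry is set by how many rods fit around the inner hole.

## Monte Carlo engine

The engine is standard Metropolis over hard particles: a sweep is $N$
attempted single-particle moves on uniformly chosen rods; a move proposes a
joint translation (uniform in a cube of side $2\,\delta_t$) and rotation
(uniform angle up to $\delta_r$ about a random axis), and accepts iff the
moved rod overlaps no other rod (axis-to-axis segment distance $< D$,
tangency allowed) and stays wall-feasible. Wall feasibility is pure
hard-core geometry: both axis endpoints clear the plates and the outer wall
by $D/2$ (sufficient for a convex wall), and the axis segment keeps
distance $R_\mathrm{inner} + D/2$ from the chamber axis. We deliberately do
*not* impose a separate centre-of-mass stand-off from the side wall: for a
curved hard wall the geometric consequence of excluded volume is a
distance $\ge D/2$ for wall-parallel rods (larger for oblique ones), and
any further constraint would be ad hoc.

Neighbour search uses an in-plane cell list keyed on rod centres with cell
edge $\ge L + D$. Two rods can only overlap if their centres are within
$L + D$, so the $3\times3$ cell neighbourhood is provably sufficient. (A
padding of $(L+D)/2$ would *not* be: centres of overlapping rods can be two
such cells apart.)

**Initialisation** is shrink–insert–inflate: all $N$ rods are inserted by
rejection sampling at a reduced diameter ($0.4\,D$ by default), then the
diameter is inflated to $D$ in stages. During inflation a move is accepted
if it does not increase the rod's total pair-overlap depth at the trial
diameter; the committed diameter advances opportunistically to the current
global clearance. This descent-on-overlap rule lets rods slide past each
other while residual overlaps shrink, which matters for the longest rods
($L/D = 25$) near the working packing fractions. A slower ramp
(`dstep = 0.01`) doubles as a quasi-static compression protocol and gives
the orientational pattern time to develop during densification. If the
clearance stops improving for `max_stage_sweeps` sweeps the initialiser
fails loudly, reporting the packing fraction actually achieved — targets
far above the feasible density (e.g. $\eta = 0.55$ at $L/D = 25$) fail this
way rather than looping forever.

Step sizes $\delta_t, \delta_r$ are auto-tuned toward 30–40 % acceptance
during initialisation only, then frozen for production (tuning during
production would break detailed balance). All randomness — insertion,
tuning, production — draws from R's global RNG, so a single
`seed` makes entire trajectories bit-reproducible.

The number of particles for a target packing fraction is
$N = \mathrm{round}(\eta\,\pi(R_\mathrm{outer}^2 - R_\mathrm{inner}^2)H /
v_\mathrm{sc})$ with $v_\mathrm{sc} = \pi D^2 L/4 + \pi D^3/6$; the
realised $\eta$ of the rounded count is recomputed by
`packing_fraction()`. Equilibration is monitored through the largest
eigenvalue $\lambda_{\max}$ of the global tensor order parameter
$\mathbf{Q} = \langle (3\,\mathbf{u}\mathbf{u}^T - \mathbf{I})/2 \rangle$,
with a two-window plateau test (`equilibrated()`).

In the strictly two-dimensional case $H = D$ the engine freezes $z = H/2$
and $u_z = 0$ exactly instead of simulating a vanishing transverse freedom.

## Sub-particle field analysis

All texture analysis runs on a square grid of cell size $\le D$ (default
$D$): each rod axis is cut into segments of length $D/2$, and each segment
deposits the 2D nematic tensor $2\hat{\mathbf{u}}\hat{\mathbf{u}}^T -
\mathbf{I}$ of its in-plane unit orientation into the cell under its
midpoint. This is an order parameter defined *below* the particle scale:
a defect core a few $D$ wide is resolved even though every rod is much
longer. In quasi-2D mode orientations are projected in-plane first (the
out-of-plane amplitude, kept as a diagnostic, is small at these
geometries). Averaging over $\gtrsim 10^3$ snapshots gives per-cell
$\mathbf{Q}$, from which $S$ (largest eigenvalue, in $[0,1]$) and the
director angle $\theta \in [0,\pi)$ follow. All angle arithmetic uses the
doubled-angle representation, the natural metric for a line field.

Singularity detection uses the **angular deficit**: at each grid vertex
the four surrounding directors are traversed as a closed loop, successive
differences are wrapped to the nematic half-turn $[-\pi/2, \pi/2)$, and
the normalised deficit $|{\sum\Delta\theta}|/\pi$ is 1 for a plaquette
containing an ideal half-integer defect and 0 on smooth plaquettes.
Above-threshold vertices (default 0.5) are clustered (single linkage, 2
cells), and each cluster's charge is the director winding along a circle
of 3 cells around the deficit-weighted centroid, rounded to the nearest
half-integer; the rounding residual is reported, and clusters whose
winding rounds to zero are discarded. The total topological charge of a
pattern is measured independently as the boundary winding along a ring
just inside the outer wall — $+1$ on a tangentially anchored disk
regardless of where the interior defects sit, $0$ net interior charge on
the annulus. The defect-sum cross-check is reported but not enforced,
because virtual defects outside the domain legitimately break it.

The local packing fraction deposits each segment's share of the rod
volume ($v_\mathrm{sc}/n_\mathrm{seg}$) into the cell slab volume
(cell area $\times H$), so its average over accessible cells reproduces
the global $\eta$; a literal projected-area fraction could not (projected
footprints overlap heavily at working densities). Statistical errors come
from contiguous block subsampling: the statistic per block, standard
deviation over $k$ blocks, divided by $\sqrt{k}$.

Directors in noisy (Monte Carlo) fields are suppressed below
`s_floor = 0.05` — at that amplitude the eigenvector is sampling noise.
Continuum fields are noise-free, so their director keeps meaning down to
the numerical floor and only truly degenerate cells are masked; this
asymmetry is intentional (an ideal defect core cell has $S$ exactly 0 on
symmetric grids).

## Pattern taxonomy

Disk patterns are classified by defect location plus a fit of the
two-defect bipolar ansatz $\theta(\mathbf r) = (\phi_+ + \phi_-)/2$
(polar angles about $(\pm a, 0)$, global axis free): two interior $+1/2$
defects give $B_i$, within the boundary band $w_b$ (default $L/2$, the
anchoring-layer scale) give $B_b$; with no interior defects the fitted
virtual separation $\hat a$ splits $B_o$ from $B_\infty$ at
$c_\infty R_\mathrm{outer}$ (default $c_\infty = 5$; the taxonomy needs
*some* cutoff for "effectively infinitely far away" and the fit plateaus
beyond a few radii). Fits use mean $\sin^2\Delta\theta$ over defined
cells — the doubled-angle least squares — with a coarse grid search and
Nelder–Mead refinement.

Annulus patterns are read from the angular structure along the
mid-annulus circle: domain walls depress $S$ and bend the director away
from the local tangent, so the combined (standardised) profile of $-S$
and tangential misalignment carries the $n$-fold signal as its $n$-th
Fourier harmonic. We read symmetry from this modulation rather than from
defect counting because for $n \ge 4$ the domain boundaries are extended
disclination walls without point-like outer defects. The winner must
dominate the runner-up by a configurable ratio $\rho$ (default 2);
profiles that are flat within `flat_floor` return the axisymmetric
sentinel `Inf`.

The **inscribed-$n$-gon rule** predicts the annulus symmetry from pure
geometry: $n$ rods of length $L$ forming a regular $n$-gon around the
hole have an axis-polygon apothem $(L/2)\cot(\pi/n)$, so thresholds are
$r_n = (L/2)\cot(\pi/n) + \mathrm{offset}$ and the predicted symmetry is
the largest $n$ with $r_n \le R_\mathrm{inner}$. The offset encodes where
the rod *surface*, cap gaps included, meets the hole; the candidate
conventions are $0$ and $\pm D/2$. We ship $+D/2$: it is the only
convention consistent with both printed reference parameter sets
(threefold at $R_\mathrm{inner} = 7.5\,D$, $L = 15\,D$ — which requires
$r_4 > 7.5\,D$, ruling out offsets $\le 0$ — and fourfold at
$R_\mathrm{inner} = 15\,D$, $L = 25\,D$), and it has a natural reading:
adjacent rods in the ring touch cap-to-cap, so the effective polygon side
is $L + D$ rather than $L$, which to leading order adds $\sim D/2$ to
every threshold.

## Continuum baseline

The contrast case is a minimal single-elastic-constant 2D Landau–de
Gennes model on the same footprints,
$$F = \int \left[\tfrac{a_2}{2}\,\mathrm{tr}\,Q^2 +
\tfrac{a_4}{4}(\mathrm{tr}\,Q^2)^2 +
\tfrac{K}{2}|\nabla Q|^2 \right] dA,$$
with strong tangential Dirichlet anchoring ($\theta = \phi + \pi/2$ at
$S_\mathrm{eq}$ on every wall) and gradient descent from a small-noise
initial state ($0.01\,S_\mathrm{eq}$; the seed breaks the degenerate
bipolar axis). With this normalisation the bulk minimiser is exactly
$S_\mathrm{eq} = \sqrt{-a_2/2a_4}$, a closed form the tests check. The
defaults $a_2 = -1$, $a_4 = 1$, $K = 1$ put the coherence length
$\xi = \sqrt{K/|a_2|}$ at one rod diameter (2.5 grid cells at the default
spacing $h = 0.4\,D$), resolving cores without stiffening the descent;
the step size is capped at $h^2/10K$ for stability, convergence is
declared when the energy decrease per iteration falls below `tol`, and
the energy trace is retained (and asserted non-increasing in the tests).
Only the topological content of these solutions is meaningful — defect
count, charges, winding — since the coefficients are conventions, not
material constants. The model reproduces the two continuum predictions
that matter for the contrast: a bipolar disk state (two antipodal $+1/2$
defects; they equilibrate at radius $\approx 5^{-1/4} R_\mathrm{outer}
\approx 0.67\,R_\mathrm{outer}$, the classical point-defect equilibrium
for strong tangential anchoring) and a defect-free, tangentially ordered
annulus. The finite-particle simulations deviate from both in
particle-size-controlled ways, which is the scientific point of the
package.

## Synthetic fixtures

Every analysis operation is testable without Monte Carlo via analytic
fields: $\theta(\mathbf r) = \theta_0 + \sum_i q_i \phi_i(\mathbf r)$
plants arbitrary half-integer defects with exact windings; `make_dn_field()`
builds $n$-fold annulus fixtures ($n$ $+1/2$ defects inside the outer
rim, $n$ virtual $-1/2$ defects inside the hole, a central $+1$ supplying
the tangential base); `rods_from_field()` dresses any field with rods at
uniform positions and field-plus-noise orientations. Fixture rods skip
the hard-core test *by design* — they are flagged `nonphysical` and used
only by orientation-space analysis, where overlaps are harmless and
placement is $O(N)$. What fixtures do not emulate: density–orientation
coupling, wall layering, equilibrium defect core structure, or any
packing physics; passing fixture tests validates the analysis chain, not
the simulation.

## Problem sizes and numerical choices

The chambers follow the reference geometry ($R_\mathrm{outer} = 40\,D$,
$H = 6\,D$, $L/D = 15$–$25$, $\eta \approx 0.2$, i.e. 300–500 particles).
The package's own test suite runs reduced problem sizes chosen for
statistical sufficiency: engine unit tests use small chambers
($R_\mathrm{outer} \approx 18\,D$, $L/D = 8$), continuum unit tests use
$R_\mathrm{outer} = 12$–$20\,D$ domains, and the pattern-reproduction
checks run the full reference geometry with $2$–$6\times10^5$ sweeps and
$\sim 10^3$ averaged snapshots — enough for the threefold annulus state to
form and be classified, while the fourfold state (slower wall dynamics,
larger rods) is additionally annealed through the slow-compression ramp.
Tie-breaks worth knowing: overlap at exactly $D$ counts as free
(measure-zero, strict inequality is cheapest); angle wrapping uses the
half-open interval $[-\pi/2, \pi/2)$; defects planted exactly on a cell
centre are jittered by half a cell; `particle_count` rounds to nearest.

## Known limitations

No cluster moves, no ensembles beyond NVT, no physical dynamics — sweep
counts measure sampling effort, not time. Disclination lines are treated
as in-plane points (the transverse direction is homogeneous at these
plate spacings). The continuum model is deliberately minimal: one elastic
constant, infinite anchoring strength; it is a topological baseline, not
a quantitative one. Pattern classification assumes converged, averaged
fields; on a coarsening snapshot it reports whatever transient structure
is present (typically `unclassified` or a non-dominant harmonic).
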