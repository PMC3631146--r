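---
title: "Modelling peri-bracket salivary flow: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling peri-bracket salivary flow: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periflow)
```

## The problem

A bonded orthodontic bracket interrupts the thin film of saliva that sweeps
the labial tooth surface during each swallow.  Where the film slows down or
recirculates, the self-cleansing action of saliva is lost, plaque
accumulates and the gingiva responds.  periflow models this system at desk
scale: a transient incompressible viscous flow over a flattened lower
central incisor carrying a bracket (and, after initial levelling, an
archwire), plus the biostatistics used to relate the flow pattern to
bacterial loads and periodontal indices at three clinical visits (T0 before
bonding, T1 one week after bonding, T2 one week after archwire placement).

## Geometry

The domain is a rectangular saliva film: mesio-distal `x`, occluso-gingival
`y` (occlusal = +y), labial protrusion `z`, with the tooth surface at
`z = 0`.  Defaults are 10 x 10 x 1.4 mm so the film holds 0.14 ml, the
saliva volume moved by one swallow; only the volume is clinically fixed,
the aspect ratio is a design choice.  The appliance is an immersed solid on
a uniform Cartesian grid (default cell 0.2 mm): a rectangular bracket prism
(width 2.4 mm, the clinical twin-bracket scale; height 3.0 mm and labial
thickness 1.0 mm are parameters, since neither is standardised at this
abstraction) and, in the T2 configuration, a 0.014-inch (0.3556 mm)
archwire cylinder spanning the domain mesio-distally at the slot height
labial to the bracket.  The 1.0 mm default thickness was chosen so the
appliance, including the wire, fits inside the 1.4 mm film; a thicker
bracket would protrude through the labial boundary.

Cells are solid when their centre lies inside the appliance.  Centres that
land exactly on an appliance boundary are included with an explicit
geometric tolerance (1e-9 mm): without it, floating-point noise in
expressions like `6.2 - 5` breaks the left-right symmetry of the mask at
some resolutions, which then contaminates every mirror-symmetry property
downstream.

The 2-mm microbial sampling band around the bracket base is partitioned
into BO (occlusal), BG (gingival), BL and BR (lateral) regions.  Band
membership is the rectangular 2-mm expansion of the footprint; each band
cell belongs to the side of the nearest bracket edge line, and corner
cells equidistant from two edge lines go to the lateral region (the
figure-level definition leaves corner ownership open; the tie-break is
deterministic and symmetric).

## Flow solver

The solver integrates mass and momentum conservation for an incompressible
Newtonian fluid, ignoring gravity:

$$\rho\left(\frac{\partial \mathbf v}{\partial t}
  + \mathbf v\cdot\nabla\mathbf v\right)
  = -\nabla p + \mu\nabla^2\mathbf v,\qquad \nabla\cdot\mathbf v = 0,$$

with saliva density 1 g/cm^3 and a water-like viscosity of 1.0 mPa s (the
viscosity is a parameter; an `eddy_factor` multiplier is exposed for
sensitivity runs with enhanced momentum diffusion).  Discretisation is a
staggered (MAC) finite-volume grid: first-order upwind advection and
explicit central diffusion form a provisional velocity, then a Chorin-type
pressure projection enforces the divergence constraint.  This replaces the
SIMPLE pressure-velocity coupling and the RNG k-epsilon closure of
industrial practice: at the appliance Reynolds number
(rho * 0.172 m/s * 2.4 mm / mu ~ 4e2) the flow is laminar-transitional, so
the solver runs laminar by default and a two-equation turbulence model is
deliberately out of scope.

The pressure-Poisson system (7-point Laplacian over fluid cells, Neumann at
walls and solid faces, periodic wrap optional in x) is factorised once per
geometry with a sparse Cholesky decomposition and reused every step, so the
divergence constraint is satisfied to machine precision rather than to an
iterative tolerance; the contract (`tol`, residual reporting) is still
honoured by checking the post-projection divergence and raising an error if
it exceeds `10 * tol * v / h`.  One pressure value per connected fluid
component is pinned to fix the Neumann nullspace.

Boundary conditions follow the model assumptions: the swallow drives the
film as a half-sine pulse, `v(t) = 0.172 * sin(pi t / 0.25 s)` m/s, entering
the upstream occluso-gingival face (the occlusal face for gingival-directed
flow and vice versa) and leaving through the opposite face with the flux
balanced exactly, so mass is conserved by construction.  The single
unidirectional pulse per swallow and the peak/duration assignment are a
reading of "flow rate represented by a sine curve"; amplitude and period
are parameters.  One printed inconsistency is worth noting: the
low-velocity threshold is defined as one hundredth of a maximal velocity
(implying 0.5 m/s) while the simulations are driven at 0.172 m/s; the
package takes the printed 0.005 m/s threshold and the printed 0.172 m/s
peak as operative.  Tooth, bracket and wire surfaces are frictionless:
free-slip is exact on the domain walls, and at the immersed mask the
tangential-direction stencil neighbours are mirrored (zero-gradient) rather
than dragged to zero.  That mirroring matters: with a naive zeroed mask the
appliance behaves as no-slip, sheds spurious corner vorticity occlusal to
the bracket, and the observed BG-only vortex pattern disappears.  A no-slip
option for the z walls is exposed for sensitivity runs and used by the
channel-flow validation.

Time stepping is adaptive: `dt = min(0.4 h / (1.1 v_max), 0.25 h^2 / nu,
T/100)`, where `v_max` tracks the current field and the imposed inflow.
The 10% headroom absorbs the within-step acceleration through the
constriction between appliance and labial boundary, which is strongest in
the T2 (wire) configuration.

## Flow metrics

Metrics are evaluated on the near-wall speed map: the velocity magnitude in
the first fluid cell layer above the tooth surface (the evaluation height
is a parameter; no physical sampling height is prescribed by the problem).
The representative field for reported metrics is the mid-cycle snapshot, at
peak inflow, when the flow pattern is fully developed; the cycle-maximum
per-cell speed map is also returned as a diagnostic of which surface cells
are ever flushed.

* **Regional average velocity** -- area-weighted mean speed per band region.
* **Low-velocity area** -- area with speed at or below 0.005 m/s (5 mm/s),
  the plaque-retention proxy.  Areas are cell counts times cell area; no
  sub-cell interpolation (simplicity, with convergence covered by the
  refinement check).
* **Vortex identification** -- connected components (4-neighbour) of
  surface cells with positive 2D Q-criterion (second invariant of the
  tangential velocity-gradient tensor) above `eps_Q = 1e-6 s^-2`.
  Gradients are mask-aware: differencing across a solid cell would
  manufacture shear out of the velocity jump to the mask, so one-sided
  differences are used next to solids.  Components are ordered by area,
  then centroid, for determinism.

When both flow directions are analysed, the combined summary takes the
arithmetic mean of the directional mean speeds and low-velocity areas and
the maximum of the directional vortex areas (vortices form under one
direction only, so averaging would halve a physically one-sided quantity;
the combination rule is otherwise unconstrained).

On the default geometry the simulated pattern reproduces the clinical
ordering: lateral regions flush fastest, the gingival and occlusal regions
are slowest, and a recirculation vortex forms gingival to the bracket only
under gingival-directed flow, with no rotation-dominated cells occlusal to
it.  Low-velocity areas at this resolution are zero: the flat synthetic
tooth lacks the curved anatomy and gingival crevice that produce the
several-mm^2 stagnant zones around a real bracket, and the slowest resolved
near-wall cells sit near 0.01 m/s.  This is exactly the kind of quantity
that passing tests do *not* certify about real anatomy; the package's
claims are about the solver's conservation properties and the qualitative
pattern, not about patient-specific areas.

## Clinical statistics

Bacterial loads are estimated from serial 10-fold dilution plating of the
1 ml transport medium: 50 ul aliquots (the clinical protocol's "50 um" is
read as a volume typo), plates countable only below 300 colonies, zero
counts flagged as below detection.  The estimate is
`log10(count * 10^k / 0.05)` CFU/ml, reported per ml of transport medium
(numerically equal to per sample at 1 ml).  Summaries use the sample SD
(n - 1); per-site n is the number of patients (27).  Site differences are
within-patient differences with paired-t p-values.  Pocket depth is
compared across visits by the paired t-test (delegated to
`stats::t.test`), the ordinal gingival index by a hand-built Wilcoxon
signed-rank test: zero differences dropped, mid-ranks for ties, exact
two-sided p by full 2^n sign enumeration for n <= 12 and a tie-corrected
continuity-corrected normal approximation above (`stats::wilcox.test`
cannot compute exact p-values under ties or zeros, so the exact path is
implemented here and cross-checked against `wilcox.test` in the tie-free
regime).  No multiple-testing correction is applied, matching the original
analysis design.

## Synthetic data

The cohort generator is the package's stand-in for clinical sampling.  Its
defaults *are* the study conditions: 27 patients; per-site log10 CFU means
and SDs from the reference per-site table (baseline 8.6332 +/- 0.0207);
GI and PD means and SDs per visit from the longitudinal table.  Values are
drawn as `mean + sd * (sqrt(rho_w) z_patient + sqrt(1 - rho_w) noise)` with
one standard-normal patient effect per measurement family, giving
within-patient correlation `rho_w` (default 0.5 -- a moderate, deliberately
unexcited choice; the true cross-site covariance is unknowable from
summary statistics, and only qualitative longitudinal behaviour depends on
it).  GI is clipped to the 0-3 scale (an ordinal rounding mode is
exposed), PD floored at zero.  Clipping makes the generator slightly
biased for GI (about +0.02 at the T0 parameters); the convergence tests
therefore compare large-cohort means against the clipped-normal mean in
closed form rather than the nominal parameter.  Plating is simulated as
Poisson counts around `density * 0.05 ml * 10^-k`.

Generators are pure functions of `(params, seed)`; the RNG state of the
caller is saved and restored.

## Numerical and testing choices

* Problem sizes: the default simulations run at 0.2 mm (50 x 50 x 7 cells,
  ~600 adaptive steps per 0.25 s swallow); validation cases use 6^3-14^3
  grids.  Grid sensitivity is measured between 0.4 mm and the default
  0.2 mm (a halving that lands on the default case): regional average
  speeds change by ~4.5%.
* The projection is verified against a dense LU solve of the identical
  Poisson system assembled independently by cell loops.
* The channel-flow limit is verified against the analytic parabolic
  profile, with the error normalised by the peak velocity (the standard
  validation norm; the pointwise relative error in the half-cell next to a
  no-slip wall is O(h) larger by construction).
* Root solves in analytic oracles use `uniroot(tol = 1e-12)`; the default
  tolerance (~1e-4 on the abscissa) is far too coarse for thresholds on
  mm-scale profiles.
* Degenerate statistical inputs (all differences zero) raise errors rather
  than returning p = 1; report assembly catches them per cell and renders
  `NA`.

## Limitations

The tooth surface is flat and rigid; there is no gingival crevice, no
bracket wings or ligature, no moving lips or mucosa, no free-surface film
thinning, and no non-Newtonian rheology.  Patient-specific flow numbers
from CT-derived anatomy are out of reach by design; the package reproduces
the mechanism (lateral flushing, gingival recirculation) rather than the
patient-averaged magnitudes.  The microbiology arm models total cultivable
counts only -- no species composition, no selective media, and no coupling
from the flow field back to bacterial growth: flow and microbiology are
related correlatively, as in the underlying study design.
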