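---
title: "Methods: free-energy, conductance and pathway analysis in permeon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: free-energy, conductance and pathway analysis in permeon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

permeon analyses single-ion permeation through wide channels along a
fixed axis.  This vignette documents the models, the parameters that
matter, the numerical choices, and what the synthetic data generator
does and does not emulate.  Units are fixed package-wide: nm, ns,
kJ/mol, elementary charges and volts; the thermal energy at 300 K is
kT = 2.494 kJ/mol.

## The Brownian-dynamics generator

All synthetic inputs come from an overdamped (Brownian)
Euler--Maruyama integrator,

$$z' = z + \beta D F(z)\,\Delta t + \sqrt{2 D \Delta t}\,\eta,
  \qquad \eta \sim N(0,1),$$

whose exact dynamics has stationary distribution
$e^{-\beta U(z)}$ — the property the downstream estimators rely on.
The total force is the potential force, the constant field force
$qE$ (1 e·V/nm = 96.485 kJ/mol/nm), an optional harmonic umbrella bias
with minimum-image displacement on periodic coordinates, and an
optional step restraint.  Full molecular dynamics is far richer, but
only the statistics of $z(t)$ matter to the analyses; the overdamped
integrator is the cheapest generator with the correct equilibrium law.

Key parameters:

* `diffusion` (nm²/ns, default 1): a generic small-ion diffusivity in
  water at 300 K (potassium is ≈2).
* `dt` (ns): must keep both the drift per step
  $\beta F_{max} D \Delta t$ and the bias stiffness
  $\theta = \beta D k \Delta t$ small.  The discretised harmonic
  variance is $kT/k \cdot (1-\theta/2)^{-1}$, so $\theta = 0.04$
  (the umbrella default, `dt = 2e-4` with k = 500) carries a 2%
  variance bias; warnings fire at drift > 0.05 nm/step or
  $\theta > 0.25$.
* `box_length` (default 14.626 nm): the axial period of the single-
  membrane simulation box the generator emulates.
* Step restraint: force of 10 000 kJ/mol/nm inside a transition
  region of half-width 0.1 nm around the boundary plane, pointing
  away from the boundary.  The half-width is a design choice (the
  emulated method states only a "narrow" region); with these defaults
  the energy wall is ~1000 kJ/mol ≫ kT and no restrained ion crosses
  in 10⁶ steps.

The umbrella generator lays `n_windows` biased windows (defaults: 209
windows, 0.07 nm spacing, k = 500 kJ/mol/nm², matching a 14.626 nm
cyclic coordinate within one spacing) and flags the first 1/6 of each
window as equilibration, mirroring a 0.1 ns discard from 0.6 ns
windows.  In-plane coordinates are drawn as independent Gaussians
with spreads `perp_spread` (default 1.2/1.2 nm, a monovalent-cation-
like bulk spread giving an effective area near 9 nm²) rather than
simulated in 3-D: their only consumer is the covariance-eigenvalue
area estimate, which is insensitive to dynamics.

**Window spacing matters.**  The window positional spread under a
500 kJ/mol/nm² bias is σ = √(kT/k) ≈ 0.07 nm.  The emulated layout
spaces windows at ≈1σ, which gives strong neighbor overlap; layouts
at ≳2σ converge slowly under WHAM and make window-level bootstrap
replicas prone to coverage gaps.  The generator warns when adjacent
window histograms do not overlap.

## Cyclic WHAM

`solve_wham()` iterates the standard self-consistency
$p(b) = \sum_i n_i(b) / \sum_i N_i f_i e^{-\beta w_i(b)}$,
$f_i^{-1} = \sum_b p(b) e^{-\beta w_i(b)}$ with bias
$w_i(b) = \tfrac{k_i}{2} d(z_b, z_i)^2$, where $d$ is the
minimum-image distance for cyclic profiles and the plain difference
otherwise.  Numerical choices:

* **Bins**: 200 over the periodic length by default — about the
  window resolution of the emulated layout.
* **Convergence**: max change of $kT \ln f_i$ below `tol = 1e-6`
  kJ/mol, `max_iter = 1e5`; the iteration count and final residual
  are stored in the profile.  The fixed point is solved in compiled
  code with the bias factors precomputed, so even 10⁵ sweeps cost
  about a second.
* **Empty bins**: a bin with no counts anywhere is a *coverage gap*
  only if it separates occupied regions (on a circle: more than one
  empty arc); gaps raise an error naming the bin centers.  A single
  uncovered arc (e.g. degenerate single-window data) simply yields
  `NA` bins.
* **Reference**: `min_zero` for display; `bulk_zero` (mean over a
  declared unbound interval shifted to zero) for binding analyses.
  Bulk intervals may wrap around the periodic seam (`lo > hi`).
* **Tie-break**: `pmf_extremum()` returns the deepest well if any
  bin is negative, else the highest barrier; exact ties go to the
  smallest |z|.

`bootstrap_pmf()` re-solves WHAM on resampled data (default 200
replicas) and attaches per-bin standard deviations after aligning
each replica to the common reference (for `min_zero`, by matching the
mean over jointly occupied bins, so the arbitrary gauge does not
inflate the spread).  Replicas are warm-started from the full
solution.  A replica that fails (gap or non-convergence) is retried
once and then counted; more than 10% failures aborts.

**Choice of bootstrap unit.**  The default resamples complete windows
— appropriate when within-window samples are autocorrelated and the
window collection itself is regarded as random.  For a *fixed* window
layout replicated with fresh dynamics, window resampling is
measurably conservative (it adds layout variability that the
replication process does not have); the within-window moving-block
bootstrap (`unit = "blocks"`, block length $n^{2/3}$) matches that
replication process and is what the package's calibration test
exercises: its per-bin error estimates fall within a factor of two of
the across-replicate scatter.  Relatedly, halving the number of
*independent* samples scales the bootstrap error by √2, but halving
an autocorrelated series by decimation barely changes the effective
sample count — and correctly leaves the error estimate nearly
unchanged.

## Standard binding free energy

With a bulk-referenced profile,
$\Delta G^0 = -kT \ln ( C^0 A \int_{bound} e^{-\beta W(z)} dz )$,
where $C^0$ = 1 molecule / 1.6606 nm³ (1 mol/L).  The integral is a
trapezoid on the profile grid with the interval endpoints
interpolated; unoccupied bins inside the bound interval are an error,
as is an interval outside the profile support.  The effective area
$A = 2\pi\xi_1\xi_2$ uses the *eigenvalues* of the 2×2 in-plane
covariance — not the marginal variances — so the estimate is
rotation-invariant.  Samples are pooled over bulk windows by default
(per-window averaging available); degenerate covariance is an error.
Useful identities, all exercised by the tests: a flat profile whose
bound volume equals the standard-state volume gives exactly 0;
scaling the area shifts $\Delta G^0$ by exactly $-kT\ln(A/A')$;
deepening any bin never weakens binding; the result diverges to
+∞ as the bound interval shrinks.  Profile errors propagate to
$\Delta G^0$ by per-bin Gaussian resampling (200 draws).

The bound interval of the emulated study, (−6.0, 7.5) nm on its axis
convention (luminal side negative), and its per-ion areas
(Ba 3.09, Ca 3.04, Mg 5.15, K 9.09, Na 3.30 nm²) ship as documented
presets; every number is overridable.

## Currents, conductance, crossings

`V = E L_z` converts the applied field to a voltage (L_z = 14.626 nm
by default).  Crossing detection unwraps the axial coordinate by
minimum image per frame pair and records signed passes of the
periodic images of the boundary plane (default: the box face at
z = 0, where crossings of the single periodic face equal
transmembrane permeation).  From wrapped data a too-coarse frame
spacing is detectable only as jumps approaching L_z/2; jumps beyond
0.45 L_z raise the unwrap-ambiguity error.  Events in the first 10 ns
are discarded by default, mirroring the emulated analysis window.
Currents are net counts × qe / duration in pA with a
√(N_f + N_b) counting error (the independent-event approximation —
the error estimator of the emulated study is unstated).  The IV fit
is ordinary least squares with a free intercept ("polynomial of first
order"), error-weighted when point errors are present, with a
proportional-fit switch; conductance is the slope in pS.

For validation, a flat-potential ensemble of N independent ions obeys
the drift-diffusion closed form $g = N q^2 e^2 D / (kT L_z^2)$,
which the acceptance checks reproduce within counting error, along
with IV linearity and field antisymmetry.

## Exit-pathway classification

The classifier works on cylindrical coordinates about the pore axis.
With band = (z_basin2, z_top): rule C fires if r exceeds r_lateral
inside the band before any upward z_top crossing; otherwise a
trajectory ending beyond z_top is B if it visited a cleft
(r > r_cleft in the band) before its last upward z_top crossing and
still had r < r_lateral at that crossing, A if it never did;
everything else (ends inside the cleft, or crosses z_top at
r ≥ r_lateral) is unclassified.  Only the final committed exit
determines the label; re-entries before it are ignored.  This
concrete rule set stands in for an unpublished heuristic; all four
thresholds are configuration values of the synthetic geometry
(defaults z_lumen = −2, z_basin2 = 1, z_top = 3, r_cleft = 1,
r_lateral = 2.5 nm), never hard-coded to a real channel.  The
branching point z_basin2 is aligned with the second free-energy basin
of the profile, where the emulated channel splits into its exits.
Raising r_cleft can only move labels toward A (monotonicity), and
identical inputs give identical labels.

The pathway generator scripts guided random walks per assigned mode
with jitter margins several σ away from every threshold, so
ground-truth labels are recoverable at >95% (not 100% — occasional
boundary grazing is intended).  Ambiguous trajectories recross
r_cleft repeatedly and end inside the cleft, exercising the
unclassified branch.  When no fractions are requested they derive
from the axial drift: the non-axial share decays exponentially in the
drift velocity, calibrated so that the 53/25/17/5 split at the
0.3 V operating point becomes ~80% axial at 1 V, echoing the
qualitative field dependence of the emulated system.

## Hydration and pore-radius profiles

Hydration numbers count solvent points within the first shell and in
the first-to-second-shell annulus per frame (minimum-image distances
in periodic boxes), binned by the ion's axial position (0.1 nm bins).
Default shell radii come from standard ion--oxygen RDF minima
(Mg 0.28/0.50, Ca 0.32/0.55, Ba 0.35/0.58, Na 0.32/0.56, K 0.36/0.60,
Cl 0.39/0.62 nm) — the emulated study states no cutoffs — and are
overridable per species.  `retained_fraction()` divides a profile by
its bulk value (declared range or number; zero bulk is an error).

The pore radius at each grid plane is the largest sphere centered
*on the axis* that touches no atom within a 0.1 nm slab: minimum over
atoms of (axial distance − atom radius), clipped at zero; empty slabs
are reported missing (`NA`), not zero.  This on-axis variant skips
the off-axis Monte-Carlo search of the full published method and
therefore underestimates the radius of non-axisymmetric pores — a
deliberate simplification, sufficient for the synthetic-geometry
oracles (a constructed cylinder of bore b and atom radius r gives
exactly b − r on interior planes).

## What the generator does not emulate

No explicit solvent dynamics, no ion--ion interactions or multi-ion
cooperativity, no membrane or protein structure, no polarization
effects.  Passing tests therefore demonstrate that the *analysis
chain* is correct against known ground truth — not that any real
channel has a particular free-energy profile, conductance or pathway
split.  Quantities that depend on the real structure (absolute
binding free energies per ion type, the 668 pS-scale conductance, the
measured pathway split, sub-nanometer constriction radii) require the
original trajectories and are documented as workflow, not reproduced.

## Problem sizes used in validation

The test-suite and acceptance runs use desk-scale problem sizes
chosen once: 51 windows × 10⁵ retained samples (dt 2·10⁻⁴ ns) for the
double-well recovery (max error comfortably below 1 kJ/mol across
seeds; at the bare 2·10⁴-sample minimum the error straddles the
bound), 20 replicate datasets × 40 block-bootstrap replicas for error
calibration, five voltages × 5·10⁵ steps × 16 ions for the
conductance check, 400 labelled trajectories for the pathway split,
and 10³ Poisson frames for hydration statistics.  Each choice keeps
the full validation under a few minutes on one CPU while leaving
multi-σ margins to the stated tolerances.

## Known limitations

* Direct WHAM iteration converges slowly when window overlap is weak
  (spacing ≳2σ); the package reports the residual and iteration count
  rather than accelerating the fixed point.
* The window-level bootstrap is conservative for fixed layouts (see
  above); choose the unit to match the question.
* The Euler--Maruyama integrator carries O(Δt) bias; the step-quality
  warnings flag the regimes where it matters.
* Crossing counting assumes a single membrane per periodic box; with
  multiple compartments the face-crossing count is not the
  transmembrane permeation count.
* The on-axis pore radius underestimates non-axisymmetric pores.
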