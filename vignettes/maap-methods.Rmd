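---
title: "maap: model, numerics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{maap: model, numerics and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science implemented by `maap`: the
reaction–diffusion model of actin photoactivation, the assumptions behind
it, the numerical scheme, and the design decisions taken where more than
one defensible choice existed. Everything quantitative stated here is
computed by the package's test suite or by `scripts/acceptance.R`; nothing
is quoted from elsewhere.

## The experiment being modeled

A 405-nm laser pulse (65 ms) converts photoactivatable fluorophores fused
to actin inside a small cylindrical region of interest (ROI) of a living
cell to their bright state. Imaging at video rate then records the decay
of the ROI's mean fluorescence for tens of seconds. Two processes drain
the signal:

1. photoactivated **G-actin** diffuses out of the ROI within the first
   one or two seconds, and
2. photoactivated **F-actin**, which is effectively immobile while it
   remains polymerized, converts to diffusible G-actin at the
   depolymerization rate $K_{dep}$ and then leaves.

The initial drop therefore reports the local G:F ratio and the late, slow
phase reports filament turnover. Both are recovered simultaneously by
matching the whole curve against forward simulations.

## Model and assumptions

Let $g(\mathbf{x},t)$ and $f(\mathbf{x},t)$ be the concentrations (µM) of
photoactivated G- and F-actin in the cytoplasmic domain $\Omega$:

$$
\partial_t g = D\,\nabla^2 g - k_{pol}\, g + K_{dep}\, f, \qquad
\partial_t f = k_{pol}\, g - K_{dep}\, f,
$$

with zero-flux boundaries on all of $\partial\Omega$ (the membrane is
closed on the time scale of the experiment). The assumptions, each of
which is also what keeps the model identifiable from a single decay curve:

- **Steady state of the bulk pools.** The total F- and G-actin
  concentrations $F_0$ and $G_0 = A_{tot} - F_0$ do not change during the
  recording, so the pseudo-first-order polymerization rate is fixed by
  detailed balance: $k_{pol} = K_{dep} F_0 / G_0$
  (`steady_state_polymerization_rate()`). A consequence used heavily in
  the implementation: because dark and photoactivated forms share all
  rates, the *total* (dark + PA) fields stay spatially uniform at
  $(G_0, F_0)$ forever, and the dark pools never need to be represented.
  The laser source during the pulse is
  $\lambda\,(G_0 - g)$ and $\lambda\,(F_0 - f)$ inside the ROI.
- **F-actin is stationary** (no retrograde flow, no filament transport)
  and **one diffusion coefficient** represents all G-actin species,
  including monomers in complex with sequestering proteins.
- **Photoactivation converts G and F with the same efficiency**, and the
  laser intensity is set so that the resident fluorophores are essentially
  fully converted by the end of the pulse
  (`laser_rate = log(1e3)/0.065` ≈ 106 s⁻¹ leaves a $10^{-3}$ dark
  residue).
- **Units** are fixed package-wide: µm, s, µM.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `D` | 3 µm²/s | G-actin diffusion coefficient |
| `A_tot` | 200 µM | total actin concentration |
| `F0` | swept 10–190 µM | F-actin concentration; G:F ratio = (A_tot−F0)/F0 |
| `K_dep` | swept 0.01–0.20 s⁻¹ | filament depolymerization rate |
| `t_pulse` | 0.065 s | activation pulse duration |
| `t_norm` | 0.035 s | normalization time (first video-rate frame) |
| `t_post` | 25 s | recorded decay duration |

The default library (`grid_spec()`) crosses 19 F values with 20 rates:
380 scenarios. A $K_{dep}=0$ row is not part of the default grid but can
be requested explicitly (`grid_spec(K_dep = c(0, ...))` fails validation
only for negative rates).

## Cell geometries

Experiments are performed in spread, substrate-attached cells. The
package provides analytic stand-ins rather than segmented images:

- **Round cell** (`make_round_cell`): footprint radius $R$, central height
  $H$, lamellipodium edge thickness $t_e$, with the dome profile
  $h(r) = t_e + (H - t_e)\,(1-(r/R)^2)^p$, $p = 2$. The exact profile is a
  modeling choice; we verified that a flat slab and the default dome give
  ROI curves differing by well under one percentage point, and the test
  suite checks that two rather different round geometries
  (20/3.5/0.3 µm and 15/7/0.4 µm) select the same library cell. What does
  matter is the *topology* of diffusion around the ROI (unrestricted 2D
  spreading), not the height details.
- **Axon** (`make_axon`): a cylinder lying on the substrate; diffusion
  out of the ROI is quasi-1D, which visibly slows the decay at identical
  kinetic parameters — the reason fits must use the geometry the data
  came from.
- **Projection cell** (`make_projection_cell`): a procedural amoeboid
  body with radial projections, used to demonstrate the same restriction
  effect; the test suite asserts its ROI decay is pointwise slower than a
  round cell's.
- **Mask import** (`make_mask_geometry`): any 3D occupancy array.

`voxelize()` classifies voxel centers on a regular grid (default
0.25 × 0.25 × 0.15 µm for the reference cell, chosen so the thin
lamellipodium edge and the 1-µm ROI are resolved) and can mesh only the
$y \ge 0$ half-space: with zero-flux boundaries everywhere, the mirror
plane through cell center and ROI center is automatically a symmetry
plane, and the test suite confirms half- and full-cell runs agree to
machine precision.

## Numerical scheme

Each time step is operator-split:

1. **Diffusion** of $g$: one backward-Euler solve
   $(I + \Delta t\, D\, L)\,g^{n+1} = g^n$ with the 7-point finite-volume
   Laplacian $L$ on interior voxels. Omitted couplings to exterior voxels
   *are* the zero-flux condition; $L$ has zero column sums, so every step
   conserves total mass to linear-solver precision (the 25-s conservation
   test observes relative drift below $10^{-10}$, against a stated
   contract of $10^{-3}$). The factorization (sparse Cholesky, CHOLMOD
   through the Matrix package) is cached per $(D\,\Delta t)$ on the grid
   object, so a 380-cell library sweep at fixed $D$ factorizes a handful
   of matrices once.
2. **Reaction**: the local 2×2 linear exchange (plus the laser source
   inside the ROI during the pulse) is advanced with its exact matrix
   exponential, which is unconditionally stable, positivity-preserving
   and conserves $g + f$ exactly outside the pulse.

Time steps are quantized so factorizations are reused: 1 ms through the
pulse and the first 100 ms of decay (the phase carrying the steep
G-actin front), then 5 ms to 0.5 s, 20 ms to 3 s and 50 ms thereafter.
The 1-ms early phase is not cosmetic: backward Euler with coarse steps
systematically *under*-estimates early diffusive loss — at 20-ms steps
the 100-ms delay loss at $D = 3$ µm²/s comes out ~7 percentage points too
low. Curves from this solver are converged: halving both the 1-ms step
and the spacing moves the normalized ROI curve by <1% pointwise (a test),
and on a flat slab the early ROI retention matches the closed-form 2D
Green's-function solution for a disc to 2% (a test, with the quadrature
oracle implemented independently in the test helper).

Decay curves are normalized by the linearly interpolated raw value at
`t_norm` = 0.035 s, mirroring normalization of experimental series to the
first recorded frame.

### What the losses look like

Because the pulse takes 65 ms and the first frame another 35 ms, a
substantial part of the activated signal is never observed. The
acceptance script recomputes, in the reference geometry:

- the fraction of the pulse-end ROI signal lost during a 100-ms delay at
  $D = 3$ µm²/s, and the same at $D = 20$ µm²/s (with the delay at which
  loss reaches 30%),
- the fraction already gone at the first frame (0.035 s), and
- the first-frame-normalized loss by 1.5 s in a diffusion-only system.

These are deterministic solver outputs; run
`Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json`.

## Fitting

`fit_curve()` is an exhaustive RMSD scan over the library on a
non-uniform grid (`fit_grid()`): 0.05-s steps to 3 s where the
diffusion-dominated drop lives, 0.2-s steps afterwards, starting exactly
at `t_norm`. Choices:

- curves shorter than the recording are compared over the overlapping
  support and flagged (`truncated`); curves not spanning the 3-s fine
  segment are rejected;
- experimental samples are aligned to the grid by linear interpolation;
- RMSD ties break deterministically to the smaller $K_{dep}$, then the
  smaller $F$;
- the nine next-best cells are reported by default, which is a practical
  way of seeing the local shape of the RMSD landscape.

`subtract_immobile_fraction()` treats the signal remaining at 2.5 s as
filament-bound and subtracts it before diffusion-only analysis. The
plateau is subtracted from the *whole* curve (not only the first 1.5 s)
to avoid a jump discontinuity; the window argument records the span over
which the correction is meaningful, and `fit_diffusion()` compares only
that early window.

`cohort_stats()` summarizes two groups of fits with box-and-whisker
percentiles (5/25/50/75/95), means with 95% CIs, a two-tailed two-sample
t-test (Welch by default; a pooled-variance switch is provided because
the classical form is common in this literature) and the within-group
Pearson correlation between $K_{dep}$ and the G:F ratio. Because fits
are grid-quantized, a cohort can be exactly constant; two constant
identical cohorts report $p = 1$, two constant different cohorts report
$p = 0$ rather than erroring, which is the informative answer for
perfectly separated groups.

## Sensitivity analysis

`differential_curves()` takes the absolute difference between library
curves adjacent along one parameter axis, time point by time point;
`time_averaged_sensitivity()` reduces each differential curve to its
unweighted mean over the fit-grid points — the times that actually enter
the fit. Differences are taken on *normalized* curves because those are
what the RMSD sees; a raw-concentration variant would only rescale the
map. The structure that emerges (and that the tests assert on a reduced
library): perturbing $K_{dep}$ is invisible in the first ~0.2 s where
decay is pure diffusion; slow-turnover differentials keep growing to the
end of the window while fast-turnover ($K_{dep} > 0.1$ s⁻¹) differentials
peak early and fade; and the time-averaged $K_{dep}$ sensitivity is
largest at high F-actin with slow turnover.

## Synthetic experiments

`generate_synthetic_curve()` emulates the acquisition chain: sample the
noise-free simulated truth at camera frame times (default 30 frames/s
starting 0.035 s after the pulse), add independent Gaussian noise per
frame with s.d. equal to `noise` × the first-frame intensity, and
renormalize to the (noisy) first frame. A master seed deterministically
derives per-curve seeds; identical seeds give bit-identical curves.

What this emulates well: frame quantization, first-frame normalization,
and the systematic distortion caused by delayed or slow acquisition — the
same truth sampled at 30 frames/s from 0.035 s versus 4.25 frames/s from
0.235 s produces visibly different apparent curves (a test), which is
why fitting must model the acquisition rather than correct for it post
hoc. What it deliberately does not emulate: photon shot noise and
detector gain (no noise-model information would support them),
photobleaching, and F-actin movement through the ROI. Passing recovery
tests therefore demonstrates the estimator's behaviour under idealized,
correctly specified noise, not robustness to every instrumental artifact.

The default noise level (2% relative) is a placeholder in the literal
sense: real curve noise varies by setup and expression level, and
`parameter_recovery_study()` takes the level as a parameter. At 2% noise,
50 replicates at an on-grid truth recover both parameters within one
grid step in well over 90% of fits (a test).

## Problem sizes used by the tests

The suite runs every physics test on a 6-µm round cell at
0.5 × 0.5 × 0.25 µm (≈850 voxels) with a 5 × 5 reduced library, and the
loss checks on the full 20-µm reference cell at the default
0.25 × 0.25 × 0.15 µm (≈91k voxels). These sizes are the package's own
verification choices: small enough to iterate on, large enough that every
claim checked coarse has also been confirmed stable under refinement.

## Known limitations

- Fits return grid cells, not continuous estimates; precision is bounded
  by the library step (10 µM in F, 0.01 s⁻¹ in $K_{dep}$). Interpolating
  the RMSD landscape is deliberately out of scope.
- The exchange model is single-rate: severing, filament-age-dependent
  disassembly and length distributions are not represented, so $K_{dep}$
  is an effective bulk turnover rate.
- Advective transport (retrograde flow) is absent; in strongly flowing
  regions the immobile-pool assumption fails.
- The library store is a plain-text container (JSON header + CSV matrix,
  17 significant digits). It round-trips doubles bit-for-bit and diffs
  cleanly under version control at the price of file size; at the default
  380 × ~300 curve points this is a few MB and was judged the right
  trade-off over a binary store.
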