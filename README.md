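# maap — modeling-assisted analysis of photoactivation

`maap` quantifies **actin monomer and filament dynamics** from
photoactivation experiments. In these experiments a pulse of 405-nm light
converts photoactivatable fluorophores (e.g. PA-GFP–actin) inside a small
region of interest (ROI) to their bright state, and the fluorescence decay
of that region is recorded. The decay mixes two processes with very
different time scales:

- fast loss as **G-actin** (monomers, diffusion coefficient *D* ≈ 3 µm²/s)
  leaves the ROI, and
- slow loss as **F-actin** (filaments, immobile on this time scale)
  releases subunits at the depolymerization rate *K*<sub>dep</sub>.

Half-time analysis cannot separate the two. `maap` instead fits each
measured curve against a **library of 3D reaction–diffusion simulations**
run in a realistic cell-shaped domain, and reads off both the local
**G:F ratio** and **K**<sub>dep</sub> simultaneously.

## Model

Photoactivated (PA) actin obeys, inside the cytoplasm Ω with zero-flux
boundaries,

```
∂g/∂t = D ∇²g − k_pol g + K_dep f   (PA-G, diffusing)
∂f/∂t =          k_pol g − K_dep f  (PA-F, immobile)
```

with the polymerization rate tied to the steady state of the bulk pools by
detailed balance, `k_pol = K_dep · F₀ / G₀`, and `G₀ = A_tot − F₀`
(total actin `A_tot = 200 µM`). During the 65-ms pulse a laser source
converts dark actin to PA inside the ROI cylinder (a 2-µm-diameter column
through the whole cytoplasm) while diffusion is already active, so the
activation and delay losses that precede the first recorded frame are part
of the simulation rather than a correction factor.

The library sweeps F-actin from 10 to 190 µM (10-µM steps) and
*K*<sub>dep</sub> from 0.01 to 0.20 s⁻¹ (0.01-s⁻¹ steps): 19 × 20 = 380
scenarios. Curves are normalized at *t* = 0.035 s (the first video-rate
frame after the pulse) and matched by RMSD on a non-uniform grid (0.05-s
steps for the first 3 s, 0.2-s steps to 25 s). See
`vignettes/maap-methods.Rmd` for assumptions, numerics and limitations.

## Worked example

Build a small library in a 12-µm round cell, generate a noisy synthetic
experiment with known ground truth, and fit it:

```r
library(maap)

geom <- make_round_cell(R = 12, H = 3, t_e = 0.3)
grid <- voxelize(geom, spacing = c(0.4, 0.4, 0.2), half_cell = TRUE)
roi  <- roi_spec(center = c(6, 0), radius = 1)

spec <- grid_spec(F = seq(60, 140, by = 20), K_dep = seq(0.02, 0.10, by = 0.02),
                  geometry_id = "round_12um")
lib  <- generate_library(spec, grid, roi, t_post = 10)

sy  <- generate_synthetic_curve(list(F0 = 100, K_dep = 0.06, D = 3),
                                grid, roi, noise = 0.02, seed = 42, duration = 10)
fit <- fit_curve(sy$curve, lib, fit_grid(end = 10))
print(fit)
head(fit$alternatives, 4)

delay_loss(3, c(0.02, 0.05, 0.1), grid, roi)
```

Output:

```
<maap_fit> F = 100 uM, K_dep = 0.06 /s (G:F ratio 1), RMSD = 0.02275 over [0.035, 9.8] s (truncated support)
    F K_dep ratio       rmsd
1 100  0.06   1.0 0.02274717
2 100  0.08   1.0 0.02714660
3  80  0.02   1.5 0.04470409
4 100  0.04   1.0 0.04620849
 0.02  0.05   0.1
0.156 0.301 0.453
```

The fit recovers the ground truth (F = 100 µM, i.e. G:F = 1, and
*K*<sub>dep</sub> = 0.06 s⁻¹) from a curve carrying 2% frame noise; the
runner-up cells show how sharply the library discriminates. ("Truncated
support" records that the 10-s recording is shorter than the full fit
grid.) The last line is the fraction of ROI fluorescence lost during
post-pulse delays of 20, 50 and 100 ms at D = 3 µm²/s in this cell —
invisible loss that first-frame normalization would silently discard.

A command-line interface wraps the same functions
(`simulate`, `build-library`, `fit`, `sensitivity`, `synth`, `recover`,
`delay-loss`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "maap.R", package = "maap"))')" \
    delay-loss --D 3 --delays 0.02,0.1
```

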