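# corrfront

Corrosion-triggered delamination is a leading failure mode of active
implantable medical devices (AIMDs): body-fluid species creep along the
metal–polymer interface of encapsulated electrodes, corrode the metal,
undermine adhesion, and eventually delaminate the silicone encapsulant —
while, in parallel, the same species diffuse through the polymer bulk
toward buried interfaces. `corrfront` is an R package plus a small
analysis workflow for studying this process quantitatively on
accelerated copper/PDMS test specimens: a droplet of encapsulant on a
corroding metal film, photographed as a time lapse, and a tilted-plate
cuvette that turns onset times into bulk diffusivities.

## What it computes

**Interface diffusion (Stefan moving boundary).** Species enter the
interface at the droplet edge from a bath at concentration `C0`, obey
Fick's second law, and are immobilized at the corrosion front `X(t)`,
which consumes an amount `S` per unit advance (Stefan condition
`S dX/dt = -D ∂C/∂x` at `x = X`). Goodman's heat-balance-integral
method with a quadratic profile

    C(x,t) = C0 [ a (1 - x/X) + b (1 - x/X)^2 ],   a + b = 1

closes the problem and yields the square-root front law

    X(t) = alpha * sqrt(t),

with `alpha` found by root-finding (`goodman_alpha()`). Two independent
oracles check it: the exact similarity solution
(`stefan_alpha_exact()`) and an explicit finite-difference solver with
a front-cell accumulator and machine-precision mass bookkeeping
(`fd_solve()`, Rcpp).

**Front tracking from images.** Frames are thresholded at a grayscale
contrast margin of 90 (Rec. 601 luminance), black pixels counted, the
protected radius derived from the circular-area formula
`r = sqrt(A/pi)`, and the front length reported as
`s(t) = r(t0) - r(t)` (`binarize()`, `estimate_radius()`,
`extract_front_trace()`).

**Three-phase segmentation.** Observed traces divide into phase I
(`alpha sqrt(t)`), phase II (delamination-driven linear advance,
continuous at the changepoint `t1`), and phase III (an artifactual jump
when bulk corrosion collapses the image contrast). `segment_phases()`
isolates the jump, then finds `t1` by exhaustive SSE search. The
delamination front trails the diffusion front at a constant lag,
`d(t) = max(0, X(t) - delta)` (`delamination_front()`), phase II moves
at the steady-state membrane rate `v2 = D C0 / (S delta)`
(`steady_state_membrane_rate()`), and `predict_merge()` compares the
interface route against bulk diffusion through the cover.

**Bulk diffusivity (tilted plate).** Layer thickness
`h(y) = offset + y tan(tilt)`, per-position diffusivity
`D = h^2 / (2 (t - lag))` (Einstein–Smoluchowski), averaged over the
maximal linear run of onset vs position, with the lag either fixed or
fitted as the intercept of `t` vs `h^2` (`estimate_bulk_D()`).

**Synthetic data.** Both experiments are forward-simulated with known
ground truth (`simulate_front_trace()`, `render_frames()`,
`simulate_cuvette()`), so every stage above is testable end to end.

## Worked example

```r
library(corrfront)

p <- stefan_params(D = 1e-6, C0 = 1, S = 10)   # cm^2/s; C0/S = 0.1
sol <- goodman_alpha(p)
sol$alpha                      # 0.0004417696 cm/sqrt(s)
stefan_alpha_exact(p)          # 0.0004400325 (0.4% from the closed form)

fd <- fd_solve(p, t_end = (0.15 / sol$alpha)^2, nx = 200)
fd$diagnostics$balance_rel_err # 1.3e-14: influx = stored + immobilized

# simulate -> render -> track -> segment
law <- composite_front_law(alpha = 1, t1 = 240, v2 = 0.05,
                           t2 = 420, jump = 250)
trace <- simulate_front_trace(law, duration = 495, step = 5)
seg <- segment_phases(trace)
seg
#> Three-phase segmentation:
#>   t1 = 240 min, alpha_hat = 1, v2_hat = 0.05
#>   phase-III contrast-collapse jump after t2 = 420 min
#>   points per phase: I = 49, II = 36, III = 15

# tilted plate: 1 mm offset, 30 deg, D = 1.676e-6 cm^2/s, 1450 min lag
geom <- plate_geometry(offset_mm = 1, tilt_deg = 30, plate_length_mm = 10)
tab <- simulate_cuvette(1.676e-6, geom, n_positions = 20, lag = 1450)
estimate_bulk_D(tab, geom, lag = "fit")
#> Bulk diffusivity: D_bar = 1.676e-06 cm^2/s over linear interval [5, 20]
#>   lag = 1450 min (fit); regression D = 1.676e-06 cm^2/s
```

The numbers mean: the closed-form front coefficient agrees with the
exact solution to 0.4% at `C0/S = 0.1`; the FD solver's mass balance
closes to round-off; the segmentation recovers the generating
changepoints exactly on noise-free data; and the cuvette inversion
returns the generating diffusivity with the 1450 min lag correctly
fitted (placing the top-edge onset at 1500 min for this geometry).

## Analysis workflow

Numbered drivers under `analysis/` run the study end to end and write
tables under `results/`:

1. `01_simulate.R` — render the droplet time lapse and cuvette table
   with ground truth.
2. `02_track_front.R` — threshold, count, and extract the front trace.
3. `03_stefan_fit.R` — closed form vs exact vs FD oracle; phase-I
   `alpha` fit.
4. `04_bulk_diffusion.R` — tilted-plate diffusivity with both lag
   modes.
5. `05_phases_and_merge.R` — segmentation, delamination lag `delta`,
   merge prediction.

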