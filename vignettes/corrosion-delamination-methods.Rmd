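---
title: "Methods: moving-boundary corrosion, front tracking and bulk diffusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: moving-boundary corrosion, front tracking and bulk diffusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corrfront)
```

`corrfront` models the degradation of encapsulated metal–polymer
interfaces in implantable devices: corroding species from the
surrounding fluid travel along the interface from the three-phase
boundary (fluid–metal–polymer), corrode the metal, weaken adhesion and
delaminate the polymer, while the same species simultaneously diffuse
through the polymer bulk. This vignette is the package's account of the
models it implements, the choices behind them, and what the synthetic
experiments do and do not establish.

## The interface-diffusion model

### Governing equations

Along the interface (coordinate $x$, cm; time $t$, s) the concentration
$C(x,t)$ of the corroding species obeys Fick's second law,
$\partial_t C = D\,\partial_x^2 C$, with a moving boundary $X(t)$
separating corroded interface ($x < X$, free diffusion) from intact
interface ($x \ge X$, $C = 0$). The boundary conditions are

* $C = 0$ at $t = 0$ for $x > 0$ (initially clean interface);
* at $x = 0$: constant bath concentration $C(0,t) = C_0$ in the default
  configuration ($l = 0$), or, with a finite surface-layer capacity
  $l > 0$, a well-stirred reservoir of depth $l$ initially at $C_0$
  depleting through the boundary flux, $l\,\partial_t C = D\,\partial_x C$;
* at $x = X(t)$: the Stefan condition
  $S\,\mathrm{d}X/\mathrm{d}t = -D\,\partial_x C$, where $S$ is the
  amount immobilized per unit front advance (the corroding species is
  consumed by the metal and withdrawn from further transport).

Sign conventions: flux into the medium at $x=0$ is positive; the Stefan
condition consumes the flux arriving at the front. The model is
one-dimensional — the circular droplet geometry is treated as radially
symmetric with a front thin compared to the droplet radius, and no
curvature correction is applied.

### Goodman's heat-balance integral

Following Goodman's integral method, a quadratic profile in the
similarity variable $\xi = 1 - x/X$,
$$C = C_0\,(a\,\xi + b\,\xi^2),$$
is required to satisfy $C(X)=0$ (automatic), $C(0)=C_0$ (so $a+b=1$),
the Stefan condition, and the spatial integral of the diffusion
equation over $[0, X]$. A quadratic term is essential: with two linear
terms the profile is degenerate and cannot satisfy three boundary
conditions. The Stefan condition gives
$\alpha^2 = 2 D \beta a$ with $\beta = C_0/S$, the integral condition
gives $\alpha^2 = 4 D b / (a/2 + b/3)$, and eliminating $\alpha$
leaves one scalar equation that `goodman_alpha()` solves by
`uniroot()` on the bracket $(0,\ 10\sqrt{2 D C_0/S}]$ (doubled up to 10
times if needed; relative tolerance $10^{-10}$). Both conditions force
the square-root front law
$$X(t) = \alpha\sqrt{t},$$
the similarity form this free-boundary problem admits; a linear-in-$t$
front would violate the integral balance. For $C_0 = 0$ the solution is
identically zero.

The exact similarity solution of the same problem,
$X = 2k\sqrt{Dt}$ with $\sqrt{\pi}\,k\,e^{k^2}\mathrm{erf}(k) = \beta$,
is implemented in `stefan_alpha_exact()` as an independent benchmark:
the heat-balance approximation is accurate to 0.2% at $\beta = 0.05$,
degrading smoothly to about 2.7% at $\beta = 1$ (computed in
`analysis/03_stefan_fit.R`).

With $l > 0$ strict similarity is impossible (a depleting reservoir has
a time scale of its own), so the closed form is returned with a warning
as the undepleted-reservoir limit, valid while the drawn mass
$\int C\,dx + S X$ is small against the capacity $l C_0$. The
finite-difference solver handles depletion fully; a test demonstrates
the front stalling when $l C_0$ is small.

### The finite-difference oracle

`fd_solve()` (Rcpp) uses explicit FTCS stepping on a fixed grid with a
front-cell accumulator: the flux arriving at the front node is
integrated, and the front advances one cell whenever $S\,\Delta x$ has
been delivered; a sub-cell front estimate
$X = (j_f - 1 + \mathrm{acc}/(S\Delta x))\,\Delta x$ removes most of
the quantization. The scheme was chosen because its mass accounting is
directly auditable: all bookkeeping uses the scheme's own discrete
fluxes, so the global balance (influx at $x=0$ = stored in profile +
immobilized) telescopes and closes to round-off ($\sim 10^{-14}$
relative); the reported residual audits the implementation. Numerical
choices: CFL number $D\Delta t/\Delta x^2 \le 0.5$ enforced (default
0.4); `nx >= 50` enforced, 200 used in the comparisons below; NaN
divergence aborts with diagnostics; the domain is sized to
$1.35\,\alpha\sqrt{t_{end}}$ by default.

Cross-validation problem sizes (chosen so the full grid runs in
seconds): a $3\times3\times3$ grid of $D \in [10^{-7}, 10^{-6}]$
cm²/s, $\beta \in [0.1, 1]$, and $l \in \{0, 50, 500\}$ cm, each run to
the time where $X$ reaches 0.1 cm on a 200-cell grid. The $l$ values
probe the closed form's validity regime ($l C_0 \gg S X$; at $l = 50$,
$\beta = 0.1$ the depletion-induced deficit is below 2%). Over the
second half of each horizon the closed form and the FD front agree
within 5% — the dominant term is the heat-balance approximation error
at $\beta = 1$, not the discretization.

The solver also supports the phase-II configuration: with
`delam_delta` set, every node behind the delamination front
$d = X - \delta$ is clamped to $C_0$ (corroding agent flooding the
opened cavity). The late-time front is then linear with slope close to
the steady-state membrane rate $v_2 = D C_0/(S\delta)$; the exact
moving-frame rate is $(D/\delta)\ln(1+\beta)$, so the discrepancy is
$O(\beta/2)$ and the numerical check uses $\beta = 0.05$.

## Front tracking from time-lapse images

Frames are converted to grayscale by Rec. 601 luminance
($0.299R + 0.587G + 0.114B$, rounded) — the conversion is configurable
(`"mean"` is also provided) because recovered traces should not and do
not depend on it for well-separated colors. A pixel is corroded when
its grayscale is *at or equal to* the contrast margin (default 90); the
boundary semantics matter and are tested. The protected area is the
non-black pixel count inside the region of interest, and
$r = \sqrt{A/\pi}$; the front length is $s(t) = r(t_0) - r(t)$,
reported raw. No morphological cleanup is applied by default (the
stage is a pure global threshold); an 8-neighbour despeckle and an
isotonic (nondecreasing) projection are available behind flags.

The ROI is a user-supplied circle, defaulting to the full frame. For
scenes with a bright background outside the specimen the ROI must
cover exactly the corroded annulus, otherwise the background inflates
the protected count; `run_analyze()` derives this circle from the
scene configuration.

## The synthetic scene

The generator emulates the droplet experiment: a bright protected disk
(initial radius $r_0$) shrinking as $r(t) = r_0 - s(t)$ inside a dark
corroded annulus on a neutral background, frames every 5 min. Defaults
mirror the reference specimen: $r_0 = 15$ mm (a 3 cm droplet) at
0.05 mm/px. Colors — protected (200, 110, 50), corroded (35, 25, 20),
background (120, 120, 120) — are rendering conventions chosen so the
margin-90 rule separates them under Rec. 601 (luminances 130, 27, 120);
they are not measured values. Noise is i.i.d. Gaussian per pixel
(clipped to 0–255) plus an optional linear illumination ramp — the
simplest model that stresses a global threshold. The renderer is
deterministic given the scene seed.

The composite front law has defaults $\alpha = 1$ px/$\sqrt{\min}$,
$t_1 = 240$ min, $v_2 = 0.05$ px/min, $t_2 = 420$ min. The 420 min
point is the artifact jump observed in this class of experiment (the
contrast collapse, phase III); the phase-II onset $t_1$ is not directly
observable and 240 min was fixed once, between the earliest interface
diffusion (within the first two hours) and the collapse. The phase-III
jump is rendered as abrupt whole-disk darkening, because it models the
threshold breaking down, not front physics.

What the synthetic tests do **not** establish: robustness to the real
droplet's wavy edge, the multi-ring structure of partially depleted
corrosion, non-Gaussian sensor noise, or drift in illumination beyond a
static ramp. Passing the round-trip bounds (≤1 px noise-free, ≤2 px at
pixel noise 5/255 on 100-frame series) shows the algorithmic chain is
exact up to rasterization, not that the threshold margin is optimal for
any particular camera.

## Three-phase segmentation

The fitted model is $s = \alpha\sqrt{t}$ on $[0, t_1]$ and a continuous
line on $(t_1, t_2]$; continuity is enforced at $t_1$ but deliberately
not at $t_2$, where the artifact jump is discontinuous. Phase III is
*detected*, not modeled: the largest forward increment exceeding 5
robust SDs, with each increment compared against the median of its
trailing window so the steep-but-decelerating $\sqrt{t}$ start cannot
masquerade as a jump, and the scale floored by the median absolute
increment so piecewise-constant increments (whose MAD is zero) do not
produce false positives. The changepoint search is exhaustive over
observed timestamps with at least `min_seg = 5` points per phase —
traces are short (hundreds of frames), so exactness beats speed. A
single-phase result is returned when the two-phase model improves SSE
by less than 5%, which also covers the degenerate SSE = 0 case.

The delamination lag $\Delta$ is treated as a free parameter: the
delamination front $d = \max(0, X - \Delta)$ becomes positive exactly
when phase II starts, so $\Delta = \hat\alpha\sqrt{t_1}$, and the
membrane relation $v_2 = D C_0/(S\Delta)$ then yields the effective
interface transport strength $D C_0/S = v_2\Delta$
(`analysis/05_phases_and_merge.R`).

`predict_merge()` compares the composite interface route (phase I to
$\Delta$, then phase II at $v_2$ across the droplet radius) with the
lag-free bulk traversal $h^2/(2 D_{bulk})$ of the cover; the earlier
route labels the failure mode, and two comparable times indicate
near-simultaneous global delamination.

## Bulk diffusion in the tilted-plate cuvette

Layer thickness $h(y) = \text{offset} + y\tan(\text{tilt})$; each
thickness acts as a membrane and visible corrosion at $y$ sets on at
$t(y) = \text{lag} + h(y)^2/(2D)$. The estimator is the standard
Einstein–Smoluchowski form $D = h^2/(2t)$ — the dimensionally
consistent reading of the relation this method is always named after.
Per-position diffusivities are averaged (arithmetic mean) over the
maximal contiguous run where onset vs $y$ is linear under an
expanding-window fit with $R^2 \ge 0.98$: onset is quadratic in $y$
over the full plate, and the linear run isolates the steady migration
regime between the early plateau and late saturation, which is where
such experiments are read. Lag handling defaults to fitting the
intercept of $t$ vs $h^2$ (the membrane time-lag construction), with a
fixed-lag mode available; the mode is always recorded.

Generator defaults: $D = 1.676\times10^{-6}$ cm²/s (the reference
average diffusivity of polysulfide ions in the silicone encapsulant,
consistent in magnitude with published small-molecule diffusivities in
the same material), offset 1 mm, tilt 30°, plate 10 mm, 20 positions,
lag 1450 min. The lag was fixed once so that the top-edge onset
($h = 1$ mm) lands at 1500 min, the reference onset for this geometry:
the bare traversal time $h^2/(2D) \approx 50$ min cannot produce a
1500 min onset by itself, so within the membrane model the difference
is necessarily lag, and the generator enforces this self-consistency
rather than leaving the printed pair contradictory. Dropping the lag
would instead require $D \approx 5.6\times10^{-8}$ cm²/s, incompatible
with the reference diffusivity by a factor of 30.

Units: tables and files carry mm and minutes (the lab's units);
physics is computed in cm and seconds; a dedicated test pins the exact
conversion factor between the two readings of the estimator.

## Reproducibility and problem sizes

Every stochastic stage takes an explicit seed and restores the
caller's RNG state. Monte-Carlo study sizes: 100 replicates for
$\hat\alpha$ (100-point traces, noise SD 0.5 px — recovery within 2%),
100 for $t_1$ (within 3 frame intervals), 50 for the fitted-lag
cuvette inversion (1% multiplicative onset noise — within 5%), and a
27-case sweep for segmentation accuracy across
$\alpha \in [0.5, 2]$, $v_2 \in [0.02, 0.2]$, noise $\in \{0, 0.5, 1\}$
px. Rendered round-trip checks use 100-frame series with a 100 px
droplet in 256 px frames; the analysis scripts use 150 px in 384 px
frames. These sizes were chosen so the whole suite and the acceptance
script each run in well under a minute of compute while leaving the
estimators' error budgets clearly resolved.

## Known limitations

* The interface model is one-dimensional; front curvature and the
  radial convergence of the droplet geometry are ignored.
* $D$, $C_0$, $S$ and $l$ enter only through $\alpha$ and $\beta$;
  absolute interface parameters are not identifiable from a front
  trace alone, so $\alpha$ is fitted, never predicted ab initio.
* Phase II is summarized by a constant $\Delta$ and a constant $v_2$;
  adhesion chemistry (surface treatments, adhesion layers) enters only
  as different fitted $(\alpha, v_2, t_1)$ presets.
* The bulk route in `predict_merge()` is lag-free and one-dimensional;
  it brackets, rather than resolves, the merge regime.
* The depleting-reservoir configuration ($l > 0$) is experimental:
  supported by the FD solver, approximated by the closed form only in
  its undepleted limit.
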