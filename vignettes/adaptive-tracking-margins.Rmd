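---
title: "Auto-adaptive tracking margins: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auto-adaptive tracking margins: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(trackmargin)
```

## The problem

In MLC-tracked radiotherapy the treatment aperture follows a moving target
(typically an abdominal or thoracic lesion modulated by breathing). The
tracking chain is not instantaneous: position sensing arrives with a latency
$\Delta T_\text{sense}$ of up to several hundred milliseconds, and the
electromechanical leaf system answers with its own complex lag, overshoots
and rate limits. The aperture therefore never sits exactly on the target,
and the shoulders of the delivered dose distribution are smeared: the target
edge is systematically underdosed.

`trackmargin` implements an on-line compensation strategy: measure the
aperture-versus-target error continuously, model its probability density,
translate that density into the dose it will cost, and widen the segment —
per side, per axis — by exactly the margin needed to restore a chosen dose
level at the field edge. Everything adapts automatically to the current
patient motion and the current machine behavior; nothing is prescribed at
planning time.

## The error model

All geometry lives in the beam's-eye view (BEV). With $p_\text{MLC}(t)$ the
aperture center of gravity realized by the machine and $p_\text{target}(t)$
the true target position, the tracking error per principal axis is
$\epsilon(t) = p_\text{MLC}(t) - p_\text{target}(t)$.

The true target position is only known with the sensing delay: the freshest
sensed sample at wall-clock time $t'$ describes the target at
$t' - \Delta T_\text{sense}$. The estimator therefore compares a *looked-back*
MLC position with the current sensed sample,

$$\hat\epsilon(t' - \Delta T_\text{sense}) =
  p_\text{MLC}(t' - \Delta T_\text{sense}) - p_\text{sense}(t'),$$

which is causal: nothing later than $t'$ is ever read
(`compute_tracking_error()`). $\Delta T_\text{sense}$ is constant per run
(300 ms by default, emulating a realistic imaging chain); the look-back
interpolation is linear, and the API would accept per-sample delays.

Errors are collected per axis in a cyclic FIFO of $N = 500$ samples. At the
40 ms control cycle that is a sliding 20 s window — long enough for stable
statistics, short enough to adapt when the breathing pattern changes.

## From samples to a density: the KDE

Histogram binning would impose arbitrary bin edges on a few hundred
samples, so the buffered errors are turned into a continuous density with a
Gaussian kernel density estimator,

$$p_\epsilon(x) = \frac{1}{N}\sum_{n} K_\sigma(x - \epsilon_n),$$

with the one-dimensional normal-reference ("rule-of-thumb") bandwidth
$\sigma = s\,(4/(3N))^{1/5}$, $s$ being the sample standard deviation
(`kde_bandwidth()`). The SD-based variant is used rather than a robust
IQR variant for determinism and simplicity. Two numerical choices:

* the density is evaluated on a fixed 0.05 mm grid spanning the samples
  ± 4 bandwidths — five times finer than the 0.25 mm raster, so that the
  margin root-finding error is far below the raster quantum;
* the evaluated density is renormalized to unit numerical integral. A bare
  kernel sum has mass $N$, and even the $1/N$-scaled version loses a little
  mass to grid truncation; unit mass is required so that the dose
  degradation below conserves integral dose exactly.

With fewer than two distinct samples the bandwidth is undefined and falls
back to the raster resolution (0.25 mm). Margins stay suspended (zero)
until a warm-up count of 50 samples (2 s) has accumulated; the start-up
behavior of the controller is otherwise unspecified and this is the
package's choice.

One known limitation: a single global bandwidth oversmooths strongly
bimodal error densities (e.g. an exactly two-state motion). For the
breathing-like errors the controller targets — skewed, heavy-shouldered,
mildly multi-modal — the rule of thumb is accurate; the test suite
quantifies L1 convergence on such a mixture.

## The dose model

The static reference dose of a segment is not a perfect block: collimator
scatter and source size produce a penumbra. This is modeled by a
shift-invariant, radially symmetric *penumbra-generating kernel* (PGK) with

$$D_\text{static,real} = \text{PGK} * D_\text{static,ideal}.$$

`estimate_pgk()` recovers the PGK from a measured static profile of a
10×10 cm² field by Fourier deconvolution. The block spectrum has
near-zeros, so the division is regularized with a *waterlevel*: denominator
bins below $10^{-3}$ of the peak magnitude are raised to that floor. Two
further clean-up steps stabilize the estimate:

* bins flagged by the waterlevel carry an essentially arbitrary ratio
  (both numerator and denominator are noise-dominated there), and leaving
  the floored value in place imprints spectral notches that ring through
  the whole kernel. Since the physical kernel is compact, its spectrum is
  smooth, and the flagged bins are repaired by linear interpolation from
  their reliable neighbors;
* a mild Gaussian apodization (SD 0.5 mm) suppresses noise amplification
  near the Nyquist frequency. The apodization variance is known exactly and
  `pgk_sd()` subtracts it again, so the reported kernel width estimates the
  physical kernel.

Finally the kernel is trimmed to its contiguous support above $10^{-3}$ of
its peak, clipped to non-negative weights, symmetrized (the physical kernel
is symmetric) and renormalized to unit integral. A noise-free synthetic
3 mm penumbra is recovered to 0.1%; with 1% white measurement noise the
error stays within a few percent. Depth dependence of the penumbra is out
of scope; the kernel is treated as constant over the tracked plane.

Tracking errors degrade the reference dose by convolution with the error
density, per axis:

$$D_\text{dyn}(x) = (D_\text{ref} * p_\epsilon)(x).$$

The orientation is fixed by the delta test: a pure error of $+s$ (aperture
displaced toward $+x$ in the target frame) moves dose toward $+x$, i.e.
$D_\text{dyn}(x) = D_\text{ref}(x - s)$.

## Margin extraction

The *confidence level* $\hat D$ (default 0.9) is the fraction of the
reference dose the controller aims to restore at the field edge. On each
side of the field the static reference and the degraded profile each cross
$\hat D$ once (the outermost crossing is used, which is conservative for
multi-modal error densities); the margin is the geometric distance by which
the degraded crossing has retreated *inward*:

$$m_+ = \max(0,\; x_\text{ref} - x_\text{dyn}), \qquad
  m_- = \max(0,\; x_\text{dyn} - x_\text{ref}).$$

A shoulder pushed outward (local overdose) needs no compensation and clamps
to zero — margins only ever expand the aperture. If the degraded profile
never reaches $\hat D$ at all (catastrophic smearing), the margin saturates
at the configured maximum (20 mm) with an explicit flag. Crossings are
located by linear interpolation between grid samples; on the 0.25 mm
profile grid this is accurate to ~0.003 mm for erf-like shoulders, which
the Gaussian closed form
$m = \Phi^{-1}(\hat D)\,(\sqrt{\sigma_p^2+\sigma_e^2} - \sigma_p)$
confirms to within 0.05 mm across $\sigma_e \in [1, 6]$ mm and
$\hat D \in \{0.8, 0.9, 0.95\}$.

Each axis is treated independently (`margins_from_state()`): the x-axis
reference profile is degraded with the x error density and solved on both
sides, likewise for y, yielding the four-component prescription
$m = ((m_{x+}, m_{x-}), (m_{y+}, m_{y-}))$. Both shoulders of one axis use
the same axis density; the per-side asymmetry comes from the asymmetry of
the density itself (e.g. faster inhale than exhale velocities).

## Applying margins to the segment

The planned segment polygon is rasterized at 0.25 mm (cell-center-inside,
even-odd rule), dilated, re-contoured and fitted to the leaf bank:

* **Dilation kernel.** Per axis the structuring element has
  `round(m/0.25)` cells on each side of a center element, with half-up
  rounding — margins of (−4, 2) mm give 16 + 1 + 8 = 25 elements. The
  rounding rule is the package's choice (it is symmetric and reproduces
  that worked example); margins are clamped to [0, 20] mm.
* **Dilation** is separable binary dilation along x then y (extensive,
  monotone, axis-order independent).
* **Contour extraction** chains the boundary edges of the occupied region
  on the cell-corner lattice, keeping the largest 4-connected component
  and discarding holes. Because vertices lie on cell corners, the
  rasterize–outline round trip is exact on the same grid.
* **Leaf fitting** subdivides each 5 mm leaf pair into 10 sub-leaf rows
  (0.5 mm effective discretization), intersects each row's center line
  with the polygon, and averages the per-row extreme positions into the
  pair's leaf tips. Rows crossed more than twice contribute their global
  extents (convex cover of the row; logged). Pairs never touched by the
  polygon close at the aperture centroid's x with zero gap — the machine
  park rule is not prescribed anywhere, and the centroid keeps closed tips
  behind the jaws. The jaws themselves sit at the polygon's y extrema plus
  the perpendicular margins.

## The virtual delivery

Real deliveries were evaluated with film; the package replaces linac and
film with a simulator so every claim is testable on a desk:

* **Motion** (`generate_trace()`): a cyclic waveform
  $A_i\,(2\sin^4(\pi\phi) - 1)$ with a rest phase at end-exhale, per-cycle
  random amplitude and period, a slow drift and a small cardiac ripple,
  generated at 10 Hz (a realistic imaging rate) and linearly upsampled to
  the 40 ms control cycle. Two presets bracket observed breathing classes:
  `"v1"` (regular, sleep-like: 6.5 mm amplitude — 13 mm peak-to-peak,
  diaphragm-scale — 4 s period, 5% cycle variability) and `"v2"`
  (irregular: 7 mm, 3.3 s, 30% variability); both mix the surrogate onto
  the BEV axes obliquely (0.96, 0.28) and add a 0.4 mm, 1.1 Hz cardiac
  component and 0.2 mm/min drift. These values are fixed study conditions,
  not tuning knobs.
* **Machine** (`respond()`): first-order lag (default time constant 80 ms)
  plus a 25 mm/s leaf-speed rate limit per axis. The real response of an
  MLC is "complex"; this model is configurable and deliberately not an
  acceptance surface. COG quantization is available but defaults to zero —
  aperture discretization enters through leaf fitting instead.
* **Dose** (`accumulate_dose()`): once per 40 ms cycle the open-aperture
  fluence is deposited in the target frame, displaced by the instantaneous
  error $\epsilon(t)$, with sub-cell displacements split bilinearly over
  the four neighboring lattice offsets; sub-cycle motion is ignored,
  consistent with the control-system granularity. The penumbra blur is a
  single 2-D convolution at the end (exact by linearity), using the
  isotropic rotation of the 1-D PGK. Maps are normalized to the mean over
  the central 15×15 mm² of the static exposure.
* **Scoring**: dose-area histograms over two regions of the static
  reference — the shoulder band $0.9 < D < 0.97$ and the plateau
  $D > 0.9$ — summarized by A90, the area fraction above 0.9.

What the simulator does *not* emulate: output-factor and head-scatter
changes with aperture position, film dosimetry and its calibration, depth
dose and 3-D scatter, gantry/collimator rotation. Passing tests show the
control loop and dose model are self-consistent under these idealizations,
not that a physical delivery would reproduce the same absolute coverage
numbers.

## The closed loop

`run_tracking_loop()` chains everything per cycle: sense (delayed target)
→ machine response → causal error estimate → KDE → margin solve → dilation
→ leaf fit → deposition, producing the four exposures of a film study
(static, untracked, tracked, tracked + margins), the per-cycle margin log
and the DAH report. Margins are recomputed every 10 cycles (0.4 s): the
density evolves on the 20 s buffer timescale, so this changes nothing
physically while keeping runtimes practical in R. Simulations in the test
suite use 120 s deliveries (3000 cycles) and a 200 s (5000 cycle) run for
the model-equivalence check; those sizes give stable DAH statistics.

Two properties close the argument:

* **Model–simulator equivalence**: the central-axis profile of a simulated
  tracked delivery agrees with the dose model applied to the empirical
  error histogram to within 2% of the plateau (measured: ~0.1%). The two
  routes are computed independently (per-cycle 2-D deposition vs. 1-D
  convolution).
* **Coverage recovery**: on both presets with 300 ms latency, shoulder A90
  with margins strictly exceeds the uncompensated value and the
  compensated 90% iso-dose region encloses the reference 90% region to
  within the 0.5 mm leaf-fitting discretization. Residual contour
  deviations concentrate at oblique field angles where the finite leaf
  width matters — the same effect a physical delivery shows.

```{r example, eval = FALSE}
cfg <- run_config(breathing = breathing_preset("v2", seed = 12),
                  duration = 120)
run <- run_tracking_loop(cfg)
glance(run)
autoplot(run)
```

## Degenerate inputs and tie-breaks

* Zero-area or collinear polygons rasterize to an empty mask (warning);
  an empty mask cannot be re-contoured (error: the aperture vanished).
* Multiple raster components: largest kept, warning.
* Touching-corner ambiguity in contour chaining: resolved toward the
  sharpest left turn, which keeps each loop tight around its own
  4-connected component.
* Zero motion: the error density collapses to the fallback bandwidth and
  the solved margins stay below the raster quantum, so the dilation kernel
  is the identity and all four exposures coincide.
* Non-finite error samples are rejected at the buffer with a warning.
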