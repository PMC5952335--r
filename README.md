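# trackmargin

Auto-adaptive tracking margins for MLC-tracked radiotherapy.

When a multileaf collimator (MLC) tracks a breathing-driven target, sensing
latency and the sluggish electromechanical leaf response leave a residual
aperture-versus-target error ε(t). The field shoulders smear and the target
edge is underdosed. `trackmargin` closes that gap on-line, during delivery:

1. **Error statistics** — the causal error estimate
   ε̂(t′ − ΔT_sense) = p_MLC(t′ − ΔT_sense) − p_sense(t′) is buffered in a
   cyclic FIFO (N = 500 samples ≙ 20 s at the 40 ms control cycle) and
   modeled per axis with a Gaussian KDE, p_ε(x) = (1/N) Σ K_σ(x − ε_n),
   bandwidth σ = s·(4/3N)^(1/5).
2. **Dose model** — the static reference dose is an ideal block convolved
   with a penumbra-generating kernel (PGK), estimated from a measured
   profile by waterlevel-regularized Fourier deconvolution; tracking
   degrades it as D_dyn = D_ref ∗ p_ε.
3. **Margin solve** — at confidence level D̂ (default 0.9) the per-side
   margin is the inward retreat of the degraded D̂-crossing,
   m = max(0, |x_ref − x_dyn|), giving m = ((m_x+, m_x−), (m_y+, m_y−)).
   For erf shoulders and Gaussian errors this reduces to the closed form
   m = Φ⁻¹(D̂)·(√(σ_p² + σ_e²) − σ_p).
4. **Segment shaping** — the planned polygon is rasterized at 0.25 mm,
   dilated with an asymmetric per-axis kernel (margins (−4, 2) mm →
   16 + 1 + 8 = 25 elements), re-contoured, and fitted to 5 mm leaves by
   sub-leaf averaging; jaws follow the perpendicular margins.

A virtual delivery (breathing-like motion synthesis, 300 ms sensing
latency, first-order-lag + rate-limited MLC, per-cycle dose accumulation in
the target frame, dose-area-histogram scoring) replaces linac and film, so
the whole closed loop is testable offline.

Intended audience: medical-physics researchers working on MLC tracking,
latency compensation and margin concepts.

## Worked example

Margins for a 50 mm field with a 3 mm penumbra under 4 mm Gaussian
tracking errors:

```r
library(trackmargin)

x   <- seq(-80, 80, by = 0.25)
ref <- dose_profile(x, pnorm((x + 25)/3) - pnorm((x - 25)/3),
                    kind = "static_real")
g    <- seq(-32, 32, by = 0.05)
dens <- tibble::tibble(x_mm = g, density = dnorm(g, 0, 4))

margins_from_state(dens, dens, ref, ref, level = 0.9)
#> <margin_spec> x: (+2.56, -2.56) mm, y: (+2.56, -2.56) mm
```

2.56 mm per side is the closed-form value Φ⁻¹(0.9)·(√(9+16) − 3) =
1.2816 · 2 = 2.563 mm: the degraded shoulder retreats 2.56 mm inward, so
the segment must grow by that much to restore 90% of the reference dose at
the original field edge.

A full closed-loop delivery on the regular-breathing preset:

```r
cfg <- run_config(breathing = breathing_preset("v1", seed = 11),
                  duration = 120)
run <- run_tracking_loop(cfg, c("static", "tracked", "tracked_margins"))
run
#> <tracking_run> 3000 cycles, 3 maps (static, tracked, tracked_margins)
#> # A tibble: 6 × 3
#>   scenario        region     a90
#>   <chr>           <chr>    <dbl>
#> 1 static          shoulder 1
#> 2 static          plateau  1
#> 3 tracked         shoulder 0.503
#> 4 tracked         plateau  0.914
#> 5 tracked_margins shoulder 0.971
#> 6 tracked_margins plateau  0.995
```

Uncompensated tracking keeps only 50% of the shoulder band
(0.9 < D_ref < 0.97) above 90% dose; the adaptive margins recover 97% of
it, at the cost of overdose outside the original segment. `tidy(run)` gives
the per-cycle log (positions, error estimates, bandwidths, margins),
`glance(run)` the one-row summary, and `autoplot()` works on traces,
densities, profiles, kernels, dose maps, DAH curves and whole runs.

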