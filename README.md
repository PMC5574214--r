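# ipadflow

Can arterial pulsations drive intramural periarterial drainage (IPAD) — the
reverse-direction flow of brain interstitial fluid along the basement
membranes (BM) inside cerebral artery walls? `ipadflow` implements a coupled
model to answer that quantitatively:

1. **Inlet waveform** — a synthetic transcranial-Doppler-like MCA velocity
   series, Fourier-averaged into one clean beat and converted to volumetric
   flux.
2. **Pulse wave** — 1D compliant-vessel blood flow on the middle cerebral
   artery and its first bifurcation (Richtmyer two-step Lax–Wendroff,
   characteristic boundary closures, three-element Windkessel outlets).
3. **Wall mechanics** — thick-walled-cylinder (Lamé) transfer of lumen
   pressure and displacement to the BM position inside the wall.
4. **BM drainage** — conservative lubrication–Darcy evolution of the BM
   layer with a valve-like mobility ($K_0$ against blood flow direction,
   $K_1 \ge K_0$ with it), plus cycle-averaged drainage metrics, valve-ratio
   and wall-position sweeps, and bisection for the reverse-flow threshold.

The headline result under the default (study) conditions: pulsations alone
pump ISF *forwards*; a strong valve reverses the direction, but the reverse
speed remains more than two orders of magnitude below the ≈ 8.33 µm/s needed
to explain observed clearance. See the methods vignette
(`vignettes/ipad-methods.Rmd`) for the model, numerics, verification and
limitations.

## Worked example

```r
library(ipadflow)

cfg <- ipad_config()            # frozen study conditions, seed 1
run <- run_ipad_pipeline(cfg)   # ~15 s: valve ratio K0/K1 = 0.01, eta = 0.5
print(run)
#> <ipad_run>
#>   valve ratio K0/K1 = 0.01, eta = 0.5
#>   cycle-mean BM flux -4.949e-01 um^3/s (reverse / IPAD), mean q1 -2.679e-04 um/s
#>   max BM width variation 25.2 Angstrom

turnover_time(run$metrics$mean_flux_um3_s)   # days to clear 280 ml at this rate
#> [1] 6548038821

sw <- eta_ratio_sweep(cfg, etas = c(0, 0.5, 1), ratios = c(0.01, 0.1, 1),
                      hemo = run$hemo)       # reuses the hemodynamic field
sw[, c("eta", "ratio", "mean_flux_um3_s")]
#>     eta ratio mean_flux_um3_s
#> 1   0.0  0.01      -1.0151569
#> 2   0.0  0.10       3.5516656
#> 3   0.0  1.00      49.2198899
#> 4   0.5  0.01      -0.4949178
#> 5   0.5  0.10       1.7315376
#> 6   0.5  1.00      23.9960917
#> 7   1.0  0.01       0.0000000
#> 8   1.0  0.10       0.0000000
#> 9   1.0  1.00       0.0000000
```

Reverse (negative) net flux needs a small valve ratio; the effect is
strongest with the BM adjacent to the lumen (`eta = 0`) and vanishes at the
stress-free outer wall. `reverse_flow_threshold()` locates the critical ratio
(≈ 0.030 under the defaults). `autoplot()` methods exist for waveforms,
velocity series, hemodynamic fields and BM states; `tidy()`/`glance()` give
long tibbles and one-row summaries.

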