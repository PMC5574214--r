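---
title: "Methods: pulse waves, wall mechanics and intramural periarterial drainage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pulse waves, wall mechanics and intramural periarterial drainage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The scientific question

Interstitial fluid (ISF) leaves the brain along the basement membranes (BM)
inside the walls of cerebral arteries, *against* the direction of blood flow —
intramural periarterial drainage (IPAD). A long-standing hypothesis is that
arterial pulsations drive this reverse transport. `ipadflow` implements a
quantitative test of that hypothesis: it couples a one-dimensional model of
pulse-wave propagation in the middle cerebral artery (MCA) and its first
bifurcation to a lubrication-reduced Darcy model of a fluid-filled BM layer
inside the arterial wall, and asks how much net reverse flow a cardiac
pressure wave can produce.

The pipeline has four stages, each usable on its own:

1. **Inlet waveform** — a synthetic, Doppler-like MCA velocity series,
   Fourier-averaged into one clean cardiac beat and converted to volumetric
   flux (`synth_doppler_series()`, `fourier_average_peaks()`,
   `velocity_to_flux()`).
2. **Pulse wave** — the compliant-vessel 1D blood-flow equations on the
   MCA + two daughters, with a bifurcation junction and three-element
   Windkessel outlets (`simulate_network()`).
3. **Wall mechanics** — transfer of lumen pressure and displacement to the BM
   position inside the wall via thick-walled-cylinder (Lamé) elasticity
   (`wall_kinematics()`).
4. **BM drainage** — a conservative finite-volume evolution of BM thickness
   under a valve-like Darcy law, plus cycle-averaged drainage metrics
   (`bm_evolve()`, `flux_metrics()`, `reverse_flow_threshold()`).

All internal units are CGS; reported drainage metrics use µm-based units.

## Stage 1: the synthetic inlet and its realism

No patient recording ships with the package; the generator stands in for one.
A single-beat template (fast systolic upstroke, sharp peak, dicrotic notch and
wave, diastolic decay) is interpolated through clinical MCA Doppler envelope
landmarks with a periodic cubic spline and replayed with per-beat amplitude
jitter, mild period jitter and additive white noise. Defaults are frozen at
healthy-adult transcranial-Doppler values: peak systolic velocity 90 cm/s,
end-diastolic velocity 33 cm/s, period 0.85 s. Converted with a flat velocity
profile over the 0.14 cm lumen, the time-mean flux is ≈ 2.9 cm³/s with a
systolic peak of ≈ 5.6 cm³/s (the analytic bound is
$v_\text{peak}\,\pi r^2 = 5.54$ cm³/s), inside the literature MCA range.

Beat segmentation detects the foot of each beat as the local minimum
preceding each maximal systolic upslope, on a 5-sample moving average and
with a refractory interval of half the median beat spacing, so that
sample-level noise cannot create spurious beats. The last ten beats are
resampled onto a common 1024-point grid, their complex Fourier coefficients
averaged, and the average inverse-transformed. By linearity this equals the
time-domain mean of the resampled beats; uncorrelated noise is suppressed by
$1/\sqrt{n}$.

Known limits: the spline template can undershoot the end-diastolic value by a
few cm/s between landmarks; jitter is stationary and Gaussian (no
respiratory modulation, no measurement dropouts); the flat-profile conversion
(`profile_factor = 1`) is an upper bound on flux for a given centreline
velocity.

## Stage 2: the 1D pulse-wave model

State $U = (A, Q)$ (cross-sectional area, volumetric flux) evolves by

$$A_t + Q_z = 0, \qquad
Q_t + \left(\frac{Q^2}{A} + \frac{f\sqrt{A_0 A}}{\rho}\right)_z = S_2,$$

with friction and geometry sources

$$S_2 = -\frac{2\pi\nu R}{\delta_b}\frac{Q}{A}
 + \frac{1}{\rho}\Bigl(2\sqrt{A}\bigl(\sqrt{\pi}f + \sqrt{A_0}\,f'\bigr)
 - A f'\Bigr)\frac{dr_0}{dz},$$

where $\delta_b = \sqrt{\nu T / 2\pi}$ is the oscillatory boundary-layer
thickness. The pressure–area law is $p = p_0 + f(1 - \sqrt{A_0/A})$ with
wall stiffness $f(r_0) = \tfrac{4}{3}(k_1 e^{k_2 r_0} + k_3)$; the wave speed
is $c^2 = f\sqrt{A_0/A}/(2\rho)$, so $c \propto A^{-1/4}$ and the
quasi-invariants are $W_\mp = u \mp 4c$ along $\lambda_\pm = u \pm c$.

**Numerics.** Interior nodes advance with the Richtmyer two-step
Lax–Wendroff scheme (second order on smooth solutions; verified observed
order ≥ 1.9). Boundary closures are characteristic-compatibility relations:
the inlet solves for $A$ given the prescribed flux by Newton iteration; each
outlet solves a 2×2 Newton system coupling the outgoing invariant to a
backward-Euler three-element Windkessel; the bifurcation solves a 6×6 Newton
system (conservation of flux, continuity of pressure, three characteristic
compatibilities) to a residual of $10^{-12}$.

**A subtlety of tapered vessels.** In a tapered vessel the $W_\mp$ are *not*
invariant along characteristics; they obey
$dW_\mp/dt = g \pm 4 c_z (u \mp c)$ with
$g = (S_2 - \partial_z B|_A)/A$, $B = f\sqrt{A_0 A}/\rho$. Omitting these
source terms in the boundary feet produces a spurious steady circulation
(the model then fails to keep $p = \text{const},\ Q = 0$ as a steady state,
although it is an exact solution of the continuous equations). The closures
include the correction; a regression test asserts the zero-inflow state stays
uniform to well under 1% of the pulse amplitude.

## Stage 3: wall mechanics

The BM sits at dimensionless depth $\eta \in [0, 1]$ in a wall of thickness
$h_w = 0.1\,r_0$ (lumen at $\eta = 0$, stress-free outer wall at $\eta = 1$).
Two thick-walled-cylinder results map the lumen state to that depth:

- the radial compressive stress carried at radius $r = a + \eta h_w$ is
  $w(\eta) = a^2(b^2 - r^2) / (r^2 (b^2 - a^2))$ of the transmural pressure
  ($w(0) = 1$, $w(1) = 0$), giving the ISF driving pressure
  $p_\text{isf} = (p - p_0)\,w(\eta)$;
- incompressible kinematics give displacement $u(r) = \xi a / r$, so the
  lumen displacement $\xi = \sqrt{A/\pi} - r_0$ reaches the BM attenuated by
  $a / (a + \eta h_w)$, defining the moving interface radius $R_i(z, t)$.

The axial gradient $p_z$ uses second-order central differences (one-sided at
the ends, exact for quadratics). These are quasi-static, linear-elastic
approximations: no wall viscoelasticity, no radial fluid exchange between
wall layers.

## Stage 4: BM drainage with a valve

The BM layer of thickness $h_{bm} \ll R_i$ is a porous medium with mobility
$K = k/\mu$ and fluid fraction $\gamma$. The lubrication reduction of Darcy
incompressibility is

$$\frac{\partial}{\partial t}\bigl(\gamma R_i h_{bm}\bigr)
 = \frac{\partial}{\partial z}\bigl(R_i h_{bm} K(p_z)\, p_z\bigr),
 \qquad q_1 = -K(p_z)\, p_z,$$

with the valve $K(p_z) = K_0$ for $p_z < 0$ and $K_1$ for $p_z \ge 0$
($K_0 \le K_1$): forward-directed gradients see high resistance, reverse
gradients low resistance — the hypothesised rectifier for IPAD. The reported
volumetric flux over the full annulus is $Q_{bm} = 2\pi R_i h_{bm} q_1$.

**Numerics.** Explicit conservative flux-form update of the line density
$m = \gamma R_i h_{bm}$ on the stored time grid: face-centred gradients,
face valve mobility, first-order upwinding of $R_i h_{bm}$. With no-flux or
periodic ends the discrete fluid volume $\gamma \sum_j R_j h_j \,\Delta z$ is
conserved to machine precision; with open ends its change equals the net
boundary flux identically. A step-size guard aborts above the advective
stability bound. The scheme's 1D reduction is verified against a 2D annular
Darcy oracle (`darcy2d_oracle()`, mapped-coordinate finite differences with
full metric terms) on squeezed tapers and travelling peristaltic waves,
agreeing to $O((W/L)^2)$ and reproducing the classical $\varepsilon^2$
peristaltic-flux scaling.

## Default (study) parameters

| group | values |
|---|---|
| vessels (Ru, Rd, L cm) | MCA 0.14/0.14/7; daughters 0.13/0.08/6.5 and 0.13/0.08/6.4, exponential taper |
| blood | $\rho = 1.06$ g/cm³, $\nu = 0.046$ cm²/s |
| wall law | $k_1 = 2\times10^7$, $k_2 = -22.53$ cm⁻¹, $k_3 = 8.65\times10^5$ g cm⁻¹s⁻² |
| Windkessel | $R_1 = 14.130$, $R_2 = 7.200$, $C_T = 2.4752\times10^{-3}$ (CGS) |
| timing | $T = 0.85$ s, 8 cycles, $\Delta t = 10^{-5}$ s, $\Delta z = 0.1$ cm, fields stored every $10^{-3}$ s |
| wall / BM | $h_w = 0.1 r_0$, $\eta = 0.5$; $h_{bm,0} = 200$ nm, $\gamma = 0.5$, $k = 10^{-10}$ cm², $\mu = 1.5\times10^{-2}$ g cm⁻¹s⁻¹, $K_0/K_1 = 0.01$ |

```{r}
library(ipadflow)
cfg <- ipad_config()          # everything above; seed = 1
run <- run_ipad_pipeline(cfg) # ~15 s on one CPU
glance(run)
```

## What the model shows under the defaults

With the valve on ($K_0/K_1 = 0.01$) the cycle-mean BM flux at mid-MCA is
**negative** (reverse, IPAD direction): $-0.49$ µm³/s, mean reverse Darcy
speed $2.7\times10^{-4}$ µm/s. With the valve off ($K_0/K_1 = 1$) the mean
flux is **positive** (+24 µm³/s): pulsations alone pump in the direction of
blood flow, so a rectifying mechanism is necessary for reverse drainage. The
critical valve ratio, located by bisection, is ≈ 0.030. Flux magnitude is
largest with the BM adjacent to the lumen ($\eta = 0$) and vanishes at the
stress-free outer wall. Across sensitivity variants
($\gamma \in \{0.3, 0.5, 1\}$, $h_{bm,0} \in \{0.1, 0.2, 1\}$ µm) the reverse
speed stays more than two orders of magnitude below the ≈ 8.33 µm/s needed
to account for observed solute clearance — the central negative result: these
arterial pulsations cannot plausibly drive IPAD at the required rate.

## Open decisions and limitations

- **Flux-reporting convention.** Metrics integrate over the full annulus
  ($2\pi R_i h_{bm}$). Values quoted per micrometre of circumference instead
  are smaller by the factor $2\pi R_i \approx 8.8\times10^{3}$ µm;
  the package always reports the Darcy speed $q_1$ alongside the flux so the
  convention can be checked independently. Under the annulus convention our
  absolute fluxes sit orders of magnitude above some published figures while
  the speeds and all structural results (signs, threshold, $\eta$ ordering)
  agree.
- **Under-specified physiology.** $\gamma$, $h_{bm,0}$, $h_w$ and the default
  $\eta$ are not uniquely fixed by the literature; defaults are physiological
  choices, and sweeps (`eta_ratio_sweep()`, the sensitivity grid) cover the
  plausible ranges.
- **BM width variation.** The computed pulse-driven width excursion is
  ~25 Å — tiny relative to the 200 nm layer, but larger than sub-Å figures
  sometimes quoted; it follows directly from conservation of $\gamma R_i
  h_{bm}$ under the computed face fluxes.
- **Model scope.** One artery and one bifurcation; rigid surrounding tissue;
  Newtonian blood with a flat-profile friction model; quasi-static elasticity;
  no osmotic or active transport. The 2D Darcy oracle checks the lubrication
  reduction, not these modelling choices.

## Reproducing the headline numbers

`scripts/acceptance.R` recomputes the six reference targets from scratch
against the installed package:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

The seed drives the inlet generator; everything downstream is deterministic.
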