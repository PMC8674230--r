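---
title: "Quantifying LLPS from capillary-flow fluorescence traces: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying LLPS from capillary-flow fluorescence traces: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 3.5)
library(capflowr)
```

## The measurement

A protein solution that undergoes liquid--liquid phase separation (LLPS)
demixes into a dense droplet phase and a dilute phase.  In a capillary-flow
experiment the (phase-separated) sample is injected continuously through a
thin thermostatted capillary past a fluorescence detector.  Two features of
the resulting trace carry the physics:

* the **baseline** between spikes is set by the freely dissolved labeled
  species, so it reports the dilute-phase concentration once calibrated
  against non-phase-separated standards of known concentration;
* each droplet transits the detection window as a **signal spike** whose
  height scales with the droplet's fluorophore content, i.e. with droplet
  volume at the dilute labeling used (no inner-filter effects).

Because the dilute-phase concentration equals the saturation concentration
at phase coexistence, tracking the baseline across conditions (crowder,
ions, nucleic acids, time) maps the phase boundary quantitatively; spike
statistics add relative droplet size distributions, kinetics and
maturation.  The same instrument measures binding affinities by Taylor
dispersion in the dilute regime.

This vignette records the models implemented, the defaults and their
rationale, the numerical choices that affect reproducibility, and what the
synthetic-data generator does and does not emulate.

## Flow physics

For pressure-driven laminar flow in a capillary of diameter $D$, length
$L$, viscosity $\mu$ and driving pressure $\Delta P$, the package uses the
standard Hagen--Poiseuille results

$$u(r) = u_\mathrm{max}\left(1 - \left(\tfrac{2r}{D}\right)^2\right),
\qquad u_\mathrm{max} = \frac{\Delta P\, D^2}{16\,\mu L},
\qquad \bar u = \tfrac{1}{2} u_\mathrm{max}.$$

Derived quantities: the **dead time** $t_0 = L/u_\mathrm{max}$ (arrival of
the fastest, centreline streamline at the detector -- about 8.1 s for the
default 75 µm × 1 m capillary at 3500 mbar with water), the **fill time**
$L/\bar u = 2t_0$ (complete exchange of the capillary content -- these are
different events and are reported separately), the Reynolds and Dean
numbers, the inertial focusing length
$L_f = \pi\mu D^2/(\rho\, U\, a^2 f_e)$, and the wall shear stress
$\tau_w = 8\bar u\mu/D$.

An `"order_of_magnitude"` mode reproduces the coarse screening chain often
used to justify neglecting inertial focusing and Dean flow
($\Delta P D^2/(8\mu L)$ reported to the nearest power of ten; focusing
length to one significant figure).  It exists for comparison with such
screening estimates only; `"physical"` is the default everywhere.
`flow_summary()` additionally carries a fixed ~2 Pa wall-shear reference
value, flagged explicitly as an order-of-magnitude literature reference
that is *not* derivable from the physical velocities; the package never
silently substitutes it.

```{r flow}
flow_summary(capillary_system())
```

## Baseline extraction and spike detection

The dilute-phase readout follows a fixed recipe, in this order:

1. **Discard** samples above $1.10\times$ the expected signal, where the
   expectation is the standard-curve prediction at the nominal total
   concentration.  This removes droplet spikes and saturated stretches.
2. **Median filter** the surviving samples with a 31-point window.  The
   window is a count of data points, not a duration, so the trace must be
   (approximately) uniformly sampled; non-uniform traces are rejected, not
   resampled silently.
3. **Fit a 4-parameter logistic** $y = \mathrm{lower} +
   (\mathrm{upper}-\mathrm{lower})/(1+e^{-k(t-t_m)})$ to the smoothed
   series.  The baseline region starts where the fit first exceeds 99% of
   its upper asymptote.  Initialization is data-driven (lower/upper from
   the 2%/98% quantiles, midpoint from the half-range crossing, rate from
   the 25--75% rise time) with Levenberg--Marquardt refinement, so
   convergence is reproducible.
4. The **baseline fluorescence** is the lower 5% quantile (type-7, linear
   interpolation between order statistics -- stated because quantile
   definitions differ) of the smoothed series inside the region, converted
   to concentration by inverting the calibration line.

Smoothing *before* the sigmoid fit keeps front location robust when spike
trains are dense or the baseline is low; spike detection then runs on the
**raw** trace: each contiguous region exceeding baseline + 0.2 FU (an
absolute offset -- the kinetics and enrichment analyses deliberately use
different, relative criteria) yields one peak at its maximum.  For a
plateaued (e.g. saturated) maximum the first sample of the plateau is the
peak time.  A peak whose raw maximum reaches the 50 FU detector ceiling is
flagged saturated and excluded from size statistics.

Spike integrals use one sampling interval of support per supra-threshold
sample, which equals the trapezoid of the piecewise-linear trace extended
to the baseline over the flanking half-intervals; for the sub-sample-wide
spikes typical of fast flow this is the quadrature that conserves the
deposited area.

## Droplet-formation kinetics

A continuously recorded kinetics trace has a drifting background, so the
baseline is estimated by Eilers-style **asymmetric least squares**:
minimize $\sum_i w_i (y_i - z_i)^2 + \lambda \sum_i (\Delta^2 z_i)^2$ with
a second-difference penalty, $\lambda = 10^4$, and asymmetric weights
($p = 0.001$ above the baseline, $1-p$ below), re-weighted for up to 20
passes.  The third parameter printed by common commercial implementations
("threshold", 0.005) is interpreted as the convergence tolerance on the
maximum relative baseline change between passes -- the one reading
consistent with an iterative re-weighting scheme; it is exposed in the
API.  The banded system is solved sparsely; the test suite checks every
iteration against a dense direct solve.

Droplets are then local maxima exceeding the local baseline by more than
1% (relative), the peak series is smoothed with a 10-peak sliding mean
timestamped at each window's median peak time, the **lag time** is the
first peak time (approaching the instrument dead time for immediate phase
separation), and the **early growth rate** is the OLS slope of the
averaged series over the first two minutes, in FU/min.

## Binding isotherms from Taylor dispersion

A small plug of labeled indicator dispersed by laminar flow reaches the
detector as a Gaussian whose temporal variance encodes diffusivity:
$\sigma_t^2 = r_c^2\, t_R/(24 D)$, with $r_c$ the capillary inner radius
and $t_R$ the residence time; the Stokes--Einstein relation
$R_h = k_B T/(6\pi\mu D)$ converts $D$ to a hydrodynamic radius.  The
temperature enters explicitly (default 293.15 K, the thermostatted
capillary temperature) because the experiments span 20--37 °C.

For an indicator binding $n$ analyte molecules with full cooperativity
(no partially occupied species -- adding one would overfit data that only
resolve the end states), the apparent radius is

$$f_b = \frac{([A]/K_d)^n}{1 + ([A]/K_d)^n}, \qquad
\frac{1}{R_h} = \frac{1-f_b}{R_{h,\mathrm{unbound}}} +
\frac{f_b}{R_{h,\mathrm{bound}}},$$

algebraically identical to the isotherm written with
$(1/K_d)^n [A]^n$ (the tests verify the identity to machine precision).
The overall association constant of $I + nA \leftrightarrow IA_n$ is
$(K_a)^n$; the reported $K_d = 1/K_a$ is the intuitive per-site
concentration scale.  The bound radius may be smaller than the unbound one
(binding-induced collapse of the indicator).  Fits run in
$\log_{10} K_d$ with positivity bounds on radii, initialized from the
lowest- and highest-concentration points and the mid-transition
concentration; standard errors come from the Jacobian, with a delta-method
transform for $K_d$.  Indicator depletion is ignored, as in the printed
isotherms: the indicator is held two orders of magnitude below the
titrated analyte range, where the approximation is good.  Unweighted
least squares is the default, with optional $1/\mathrm{SD}^2$ weights.

```{r binding, fig.alt = "Fitted 1:2 binding isotherm"}
truth <- binding_model(2, kd_um = 5.3, rh_unbound_nm = 2.3, rh_bound_nm = 0.8)
tit <- tibble::tibble(analyte_um = c(0, 1, 2, 4, 6, 10, 20, 50, 100, 358),
                      rh_nm = binding_isotherm(truth, analyte_um))
fit <- fit_binding(tit, stoichiometry_n = 2)
tidy(fit)
```

## Relative enrichment

Two samples of identical composition are measured, differing only in which
species carries the label.  For each, the droplet-phase signal fraction is
$\mathrm{Ratio} = \sum(\text{peak areas})/(\text{total curve area})$ with a
0.5% relative peak criterion, and the quotient of the two ratios is the
relative enrichment of A over B inside droplets.  Both numerator and
denominator are fractions of their own label, so the dense-phase volume
fraction cancels and never needs to be measured.  The total curve area
(including peaks) is the denominator, by trapezoidal quadrature on the
native grid.

## Relative droplet sizes and the flow model

Spike height scales with droplet volume, so **relative diameters** are
$h^{1/3}$ normalized to median 1; no absolute calibration in µm is
attempted, because transit-time bias makes only the *relative*
distribution trustworthy.  That bias is modelled explicitly: a particle at
radius $r$ rides at $u(r)$ and its integrated signal is proportional to
its residence time, i.e. to $1/u(r)$.  With particles randomly distributed
over the cross-section, two radial flux laws are implemented:

* `"empirical"` (default): flux $\propto (1 - r/R)^2\, r$, the law used to
  fit monodisperse 1-µm calibration-sphere data;
* `"poiseuille"`: the standard flux weighting $\propto (1-(r/R)^2)\, r$.

The two differ ($(1-x)^2$ vs $1-x^2$) and the package takes no position on
which is physically right -- both are exposed, the default reproduces the
published calibration fit, and closed-form CDFs
($6x^2-8x^3+3x^4$ and $2x^2-x^4$) make sampling and testing exact.
Pushing either density through $s = u_\mathrm{max}/u(r)$ gives the
relative intensity distribution of a monodisperse population: a hard lower
bound at the centreline intensity $s = 1$, then a long right tail from
slow near-wall particles.  `fit_sphere_calibration()` convolves this with
a mean-1 lognormal intrinsic-brightness factor (CV as a parameter;
observations below the flow-model minimum are attributed to this spread)
and fits a single intensity scale by maximum likelihood, reporting a
Kolmogorov--Smirnov distance as goodness of fit.

```{r intensity, fig.alt = "Predicted relative intensity distributions"}
plot_intensity_model(s_max = 6)
```

## The synthetic trace generator

Every analysis stage is validated against simulated traces with known
ground truth.  A simulated trace is front + flat baseline + droplet spikes
+ Gaussian detector noise, clipped at the 50 FU ceiling:

* **Front.** The default front is a 4-parameter logistic with midpoint
  $1.2\,t_0$ and rate $10/t_0$, reaching 99% of the plateau by about
  $1.7\,t_0$ -- i.e. a few seconds after the dead time, matching observed
  settle times and keeping simulated acquisitions around a minute.  The
  ideal plug-geometry fill fraction $f(t) = \max(0, 1 - t_0/t)$ is
  available as `front_mode = "hydrodynamic"`; it is exact for the front
  shape but approaches its plateau only on impractically long horizons, so
  it is not the default.
* **Droplets.** Entry times are uniform after the front settles; radial
  positions follow the selected radial flux law; volumes are lognormal
  (positive and right-skewed, as observed droplet distributions are;
  `meanlog`/`sdlog` are part of the ground truth).  A droplet's spike has
  amplitude `brightness × volume` and residence duration
  `detection_window / u(r)`.  Every sample inside the residence window is
  raised by the full amplitude; a spike narrower than one sampling
  interval lands on the nearest sample at full amplitude.  Peak *height*
  is the observable that encodes droplet volume, so deposition preserves
  amplitude rather than area; the simulator returns per-event deposited
  areas so that conservation can still be book-kept exactly.  Overlapping
  spikes add linearly before clipping, as fluorescence does.
* **Noise and saturation.** Additive Gaussian noise (default 0.05 FU) and
  a hard ceiling at 50 FU, matching the detector.
* **Taylorgrams.** Gaussian plugs with
  $\sigma_t^2 = r_c^2 t_R/(24D)$, $D$ from Stokes--Einstein at the
  configured temperature; a peak narrower than 3 sampling intervals is a
  sampling-rate error rather than a silent aliasing hazard.
* The detection-window length is not a published quantity; the default is
  50 µm, configurable.
* All randomness is seeded; a missing seed on a stochastic simulation is a
  hard error, and identical seeds give bit-identical traces.

What the generator does **not** emulate: droplet deformation or breakup in
shear (treated only as an order-of-magnitude screen), inner-filter
effects, slow detector response, photobleaching along the capillary,
baseline drift within a single injection (the kinetics module handles
drifting baselines, but the standard generator produces flat ones), and
correlated noise.  Passing recovery tests therefore demonstrate the
correctness of the analysis pipeline under the stated signal model, not
robustness to every instrumental artifact of real traces.

## Problem sizes and tolerances

The validation studies use 60--120 s traces at 10 Hz (601--1201 samples),
120--250 droplets per phase-separated trace, 100 noisy replicates for the
binding recovery study, 15 replicate pairs for enrichment, $10^6$
Monte-Carlo draws for the flow-model comparison, and $n = 200$ for the
ALS-vs-dense-solve check -- sizes chosen so each study resolves its
acceptance tolerance comfortably while the whole suite runs in seconds.
Key numerical settings, collected: logistic and Gaussian fits use
Levenberg--Marquardt with tight (1e-10--1e-12) relative tolerances;
quantiles are type 7; the median filter window is 31 points; the ALS
penalty is order-2 with $\lambda = 10^4$, $p = 0.001$, convergence 0.005,
at most 20 passes; peak criteria are 0.2 FU absolute (dilute-phase
spikes), 1% relative (kinetics) and 0.5% relative (enrichment) -- three
deliberately different criteria, each as printed for its analysis.

## Known limitations

* Dilute-phase concentrations are only as good as the standard curve;
  standards must not be phase separated (a non-positive fitted slope is
  treated as that failure mode).
* The 99%-of-asymptote rule opens the baseline region slightly before the
  front has fully settled, so noise-free recovery is exact only to ~0.1%;
  this is inherent to the recipe, not a fitting artifact.
* Saturated spikes censor the intensity distribution; statistics exclude
  them, and heavily saturated samples (e.g. large calibration spheres)
  give skewed distributions that the package flags rather than corrects.
* The 1:n binding models assume full cooperativity and no indicator
  depletion; they are transition-scale descriptions, not microscopic
  binding schemes.
* Relative enrichment assumes the fluorophore quantum yield is the same
  inside and outside droplets for both labels.
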