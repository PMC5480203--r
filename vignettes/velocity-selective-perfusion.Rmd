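---
title: "Velocity-selective excitation for hyperpolarized first-pass perfusion: models, phantom and analysis choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Velocity-selective excitation for hyperpolarized first-pass perfusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsperf)
```

## The problem

First-pass myocardial perfusion imaging with hyperpolarized ^13^C urea faces a
specific obstacle: the left- and right-ventricular blood pools carry far more
tracer than the myocardium, and at practical in-plane resolutions their signal
contaminates the myocardial sectors. Dephasing the blood signal with strong
gradients works, but destroys the very magnetization that must later perfuse
the myocardium — hyperpolarized magnetization is non-renewable, decaying with
T~1~ and with every RF pulse.

The method modeled here replaces the single excitation pulse with a 1–1
binomial pair (two pulses of flip angle $\alpha$, nominally $2\times30^\circ$
instead of one $60^\circ$ pulse) separated by a bipolar gradient. A spin
moving through-plane at velocity $v$ accrues phase
$\varphi = \gamma\, m_1 v$ between the two pulses, where
$m_1 = \int G(t)\,t\,dt$ is the gradient first moment. Scaling the bipolar
pair so that $\gamma\, m_1 v_{enc} = \pi$ makes the second pulse *tip back*
the magnetization of spins moving at the encoding velocity $v_{enc}$:
blood is left unexcited **and** unsaturated, while quasi-static myocardium is
excited with the full composite flip. The relative excited amplitude and the
preserved longitudinal fraction are

$$
s(v) = \left|\sin\!\left(\frac{v_{enc}-v}{v_{enc}}\frac{\pi}{2}\right)\right|,
\qquad
M_z(v) = \left|\cos\!\left(\frac{v_{enc}-v}{v_{enc}}\frac{\pi}{2}\right)\right|,
$$

with $s^2 + M_z^2 = 1$ by construction.

```{r profile, fig.width=6, fig.height=3}
prof <- excitation_profile(c(30, 50), seq(-20, 70, by = 0.5))
autoplot(prof)
```

### A note on the relative $M_z$ form

$M_z(v)$ above is a *tip-back fraction relative to conventional excitation*,
and reads 0 at $v = 0$ even though an in-phase $2\times30^\circ$ pair really
leaves $\cos 60^\circ = 0.5$ of the longitudinal magnetization. We keep the
relative form verbatim because it is the quantity the field quotes (e.g.
"93% preserved blood-pool magnetization"); the absolute state of the
magnetization vector is available from the exact rotation composition
`bloch_binomial()`, which composes
$R_x(\alpha)\,R_z(\varphi)\,R_x(\alpha)$ on the equilibrium state. For
$\alpha = 30^\circ$ the normalized Bloch transverse magnitude deviates from
$s(v)$ by at most 0.061 (near $\varphi = \pi/2$); this is an exact property
of the finite-flip composition, not a numerical error, and the package treats
the Bloch result as the ground truth wherever absolute amplitudes matter (the
phantom simulator uses it per pixel).

## Gradient design

`design_bipolar()` returns the minimum-duration trapezoidal bipolar pair
reaching $|m_1| = \pi/(\gamma v_{enc})$ under hardware limits (defaults
30 mT/m, 200 T/m/s, the clinical system class this method targets). The
optimum has a closed form: ramping at maximum slew, a triangular lobe of
amplitude $(m_1 S^2/2)^{1/3}$ is both minimum-duration and minimum-amplitude
when it fits under the amplitude ceiling; otherwise the lobe saturates the
amplitude and the plateau solves $(r+p)(2r+p) = m_1/A$. A brute-force grid
search over candidate amplitudes serves as the independent oracle in the test
suite. Any moment is reachable by plateau extension, so infeasibility only
arises from non-positive limits.

The echo-time model is `TE = base_te + gap/2` with
`gap = bipolar duration + rf_gap_overhead`: the effective excitation center
moves to the midpoint between the two pulses, shifting the echo by half the
gap. `rf_gap_overhead` (default 3.1 ms) lumps the RF pulse halves and
slice-select/rephase lobes, calibrated once so that the designed gap at
$v_{enc} = 50$ cm/s is ≈ 6.8 ms; only orderings and approximate scale of
TE are meaningful, since actual RF durations are hardware-specific.

```{r design}
tidy(design_bipolar(50))
te_penalty(c(25, 38, 50))
```

## The digital cardiac phantom

`simulate_series()` generates a mid-ventricular short-axis slice: circular LV
cavity, six-sector myocardial annulus (60° sectors counterclockwise from the
anterior RV insertion, as in the basal/mid rings of the 16-segment AHA
model), and an RV crescent along the septum. Defaults: 64×64 matrix over a
110 mm field of view, 60 frames at one frame per heartbeat (120 bpm under
stress, TR 0.5 s — 30 s of imaging, sized so the last 10 frames are
post-bolus), imaging starting 7 beats after injection.

Per-pixel through-plane velocities are drawn once per series (the trigger
phase is fixed): LV $\mathcal N(33.4, 6.2^2)$ cm/s and myocardium
$\mathcal N(-0.82, 5.2^2)$ cm/s, the early-systolic values measured under
dobutamine stress. Two parameters are free because no measurement exists for
them: the RV distribution (default $\mathcal N(25, 8^2)$ cm/s, plausibly
slower than the LV at the same phase) and a trabecular boundary layer
(default 15% of the cavity radius with a linear taper to zero at the wall),
which reproduces the residual LV rim signal that slow near-wall flow causes
in vivo.

The signal model per frame multiplies, pixelwise:

* bolus/tissue tracer concentration — gamma-variate arterial input
  $a\,t^b e^{-t/c}$ (defaults $b = 3$, $c = 0.6$ s, arrival 1.5 s: a sharp
  stress bolus) and a one-compartment tissue model
  $c_{myo}(t) = \mathrm{MBF}\int \mathrm{AIF}(\tau)
  e^{-(t-\tau)\mathrm{MBF}/\lambda}d\tau$ with MBF 4 mL/g/min and
  $\lambda = 0.95$ mL/g. These were tuned once so the myocardial
  concentration peak lags the LV peak by 2–3 s, the physiological timing, and
  then frozen;
* polarization (0.29 at injection) and T~1~ decay (34 s, urea in blood at 33%
  dilution);
* RF usage: blood is fully replaced in-slice between beats at stress
  velocities and accrues no depletion; tissue residue is multiplied each
  frame by the per-shot longitudinal survival factor at the pixel's velocity.
  We deliberately apply depletion to the *residue only* inside the uptake
  recursion — multiplying the whole concentration history by the cumulative
  factor would also deplete freshly arrived magnetization that never saw the
  earlier pulses, and suppresses the myocardial first pass to numerical
  noise;
* per-pixel excitation amplitude — exact Bloch transverse magnitude at the
  pixel velocity (velocity-selective mode) or $\sin 60^\circ$ (conventional);
* $e^{-TE/T_2^*}$ with $T_2^* = 25$ ms (not a measured value; only the TE
  *difference* between modes matters downstream);
* an in-plane Gaussian point spread (FWHM 2 px) standing in for the
  single-shot readout resolution. This is the mechanism that produces
  blood-pool spillover into the sectors bordering the cavities — without it
  the conventional-mode curves would be implausibly clean and the
  homogeneity comparison between modes meaningless;
* optionally a linear coil-sensitivity plane, then complex Gaussian noise
  followed by the magnitude (Rician), with $\sigma$ expressed as a fraction
  of the peak noiseless conventional-mode LV signal so both modes see the
  same absolute noise.

All randomness flows from the single protocol seed; identical configurations
are bit-identical. What the phantom does **not** emulate: cardiac motion and
contraction, respiration, EPI k-space artifacts (ghosting, partial Fourier),
and multi-coil combination. Tests passing on this phantom therefore validate
the pipeline's arithmetic and the method's velocity-contrast mechanism, not
robustness to motion or reconstruction artifacts in real data.

```{r phantom, fig.width=6, fig.height=4}
ds <- simulate_series(phantom_config(protocol = acquisition_protocol(seed = 1)))
autoplot(ds, frames = c(8, 10, 13, 20))
```

## Quantification pipeline

`extract_curves()` averages the series over each sector and the LV mask and
subtracts the global magnitude offset (mean of the last 10 frames for
hyperpolarized series, whose signal has fully decayed; mean of the pre-bolus
frames for a contrast-agent series). `plane_fit_correction()` divides out a
least-squares plane fitted to the myocardium of a reference frame when a
coil profile is present.

Hyperpolarized sector curves are fitted with the three-parameter
gamma-variate; contrast curves with a fourth-order polynomial. The
gamma-variate fit uses Levenberg–Marquardt with positivity bounds
($b \le 10$), log-linearized initialization, tolerance 10⁻⁸, max 500
iterations; non-convergence is a flag on the result, never an exception,
so a failed sector does not abort a study. The first-pass window opens at
the first frame where the LV curve exceeds 5× its baseline SD and closes at
the later of the fitted myocardial peak + 3c or the LV curve falling below
10% of its peak — the window definition is operational because the source
analysis only states that it was restricted to the first pass.

Semi-quantitative measures per sector, computed from the *fitted* curves for
both modalities (the operational choice when the source is silent):

* **AUC** — closed form $a\,c^{b+1}\Gamma(b+1)$ for a full-pass
  gamma-variate, numeric quadrature otherwise;
* **pCNR** — fitted peak over the noise SD;
* **upslope** — maximum first derivative of the fitted curve between arrival
  and peak (an operational definition; "upslope" is not otherwise defined);
* **SNR** — mask mean over the noise SD estimated as
  $\mathrm{sd}(\text{difference of two noise frames})/\sqrt2$; default noise
  frames are the last two (hyperpolarized) or first two (contrast);
* **CNR** — peak SNR minus mean baseline SNR;
* **CoV** — sample SD over mean across the six sectors, per metric.

Mode comparisons use the paired two-sided Wilcoxon signed-rank test, exact
for $n \le 25$ without ties (at the $n = 6$ scale of a typical animal study
the one-signed exact two-sided p is $2/2^6 = 0.03125$).

```{r metrics}
pm <- perfusion_metrics(ds)
tidy(pm)
glance(pm)
```

## Numerical and degenerate-input choices

* Gauss–Hermite quadrature (default 96 nodes, ≥ 64 required) for the mean
  preserved magnetization; converged to < 10⁻⁶ against adaptive quadrature.
* The first moment of rendered waveforms uses trapezoidal quadrature on a
  densely sampled piecewise-linear waveform (200 points per segment), keeping
  the design/measure round-trip below 0.1% error by a wide margin.
* Degenerate inputs fail loudly and early: non-monotone time axes, empty or
  collinear plane-fit masks, zero-thickness myocardium, zero noise variance
  and all-zero difference vectors are classed errors (`vsperf_invalid_input`,
  `vsperf_fit_error`, ...) rather than NaN propagation; the two deliberate
  exceptions are the gamma-variate non-convergence flag and the all-zero
  Wilcoxon case (p = 1 with a warning), both of which must not abort batch
  analyses.
* Ties in the sector labeling at exact 60° boundaries go to the lower sector
  index; sector pixel counts agree within boundary-pixel tolerance.

## Known limitations

* The closed-form profiles treat velocity as constant between the two RF
  pulses (~7 ms apart); acceleration and intra-voxel velocity distributions
  enter only through the pixelwise Gaussian draws.
* The tissue model is a deliberately simple one-compartment uptake; it is a
  vehicle for testing the measurement pipeline, not a physiological claim.
  Absolute MBF quantification is out of scope.
* The conventional-mode cross-sector variability in the phantom (~10–13%)
  is smaller than reported in animals (28–93%): the phantom has no motion,
  no reconstruction artifacts and uniform true MBF, so only the
  spillover-driven part of the inhomogeneity is reproduced. The *ordering*
  (velocity-selective < conventional) is the property the package asserts,
  and it holds in ≥ 18/20 seeded replicates.
* Echo-time absolute values depend on unpublished RF/slice-select timings and
  are matched in ordering and scale only.
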