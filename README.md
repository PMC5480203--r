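# vsperf

Simulation and quantification toolkit for **velocity-selective binomial
(1–1) tip-back excitation** in hyperpolarized ^13^C urea first-pass
myocardial perfusion CMR.

Hyperpolarized perfusion imaging of the heart has a blood-pool problem: the
ventricular cavities hold far more tracer than the myocardium, so cavity
signal bleeds into the myocardial sectors — but dephasing the blood wastes
the non-renewable hyperpolarized magnetization before it can perfuse the
tissue. The velocity-selective scheme splits the excitation into two pulses
of flip α separated by a bipolar gradient whose first moment `m1` satisfies
`γ · m1 · v_enc = π`. Spins moving through-plane at the encoding velocity
`v_enc` acquire phase π between the pulses and are tipped *back* to the
longitudinal axis — unexcited and unsaturated — while quasi-static
myocardium receives the full composite flip. The excited and preserved
fractions as a function of velocity are

    s(v)  = | sin( ((v_enc − v)/v_enc) · π/2 ) |
    Mz(v) = | cos( ((v_enc − v)/v_enc) · π/2 ) |,   s² + Mz² = 1.

The package is aimed at sequence developers and perfusion-analysis authors
who need (a) the closed-form and Bloch-simulated physics of this excitation,
(b) minimum-duration bipolar gradient design under hardware limits, (c) a
seeded digital short-axis cardiac phantom producing realistic dynamic series
in both excitation modes, and (d) the semi-quantitative perfusion pipeline:
six-sector AHA curve extraction, gamma-variate / polynomial fitting,
AUC / pCNR / upslope, difference-image SNR, CNR, cross-sector coefficients of
variance, and paired Wilcoxon comparisons. Everything takes and returns
tibbles where the data are tabular, with `tidy()` / `glance()` /
`autoplot()` methods on the fitted objects.

## Worked example

Design the encoding gradient for `v_enc` = 50 cm/s on a 30 mT/m, 200 T/m/s
system:

```r
library(vsperf)
design_bipolar(50)
#> bipolar velocity-encoding pair (13C, venc 50.0 cm/s)
#>   lobe 30.00 mT/m, ramp 0.150 ms, plateau 1.541 ms, total 3.68 ms
#>   |m1| 9.338e-08 T s^2/m
```

The pair lasts 3.68 ms; with the RF/slice-select overhead this puts ~6.8 ms
between the two pulse centers and raises the echo time from 10.2 ms to
`te_penalty(50)` ≈ 13.6 ms.

Simulate a stress first-pass series in each mode (64×64, 60 heartbeats at
120 bpm, LV blood N(33.4, 6.2²) cm/s, myocardium N(−0.82, 5.2²) cm/s) and
compare the blood-pool peaks:

```r
ds_vs <- simulate_series(phantom_config(
  protocol = acquisition_protocol(mode = "velocity_selective", seed = 1)))
ds_c  <- simulate_series(phantom_config(
  protocol = acquisition_protocol(mode = "conventional", seed = 1)))
peak_lv <- function(ds) {
  cur <- extract_curves(ds$series, ds$labels, times_s = ds$times_s)
  max(cur$signal[cur$compartment == "lv"])
}
peak_lv(ds_c) / peak_lv(ds_vs)
#> [1] 3.5
```

The velocity-selective mode suppresses the LV blood-pool peak 3.5-fold while
preserving ~96% of the longitudinal blood magnetization
(`100 * mean_preserved_mz(33.4, 6.2, 33.4)` → `95.8`). Quantify the
velocity-selective series:

```r
pm <- perfusion_metrics(ds_vs)
glance(pm)
#> # A tibble: 1 × 5
#>   cov_auc cov_pcnr cov_upslope  noise_sd n_converged
#>     <dbl>    <dbl>       <dbl>     <dbl>       <int>
#> 1  0.0711   0.0505      0.0692 0.0000530           6
```

`tidy(pm)` returns the per-sector table (AUC, pCNR, upslope, SNR, CNR and
the gamma-variate peak for each of the six AHA sectors; here SNR ≈ 39–54 and
all six fits converge). The CoV row says the six sectors agree within ~5–7%
for each metric on this uniform-flow phantom; running the same analysis on
the conventional-mode series gives systematically higher CoV because the
unsuppressed blood pool contaminates the sectors bordering the cavities.

A command-line wrapper with `profile`, `design`, `simulate`, `analyze` and
`compare` subcommands is installed at `inst/cli/vsperf` (series and label
maps as NIfTI-1, curves as CSV, metrics and provenance as JSON):

```sh
Rscript inst/cli/vsperf design --venc 50 --out design.json
```

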