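# rpdlf — simulation and time-domain fitting of R-PDLF NMR dipolar modulations

Proton-detected local-field (PDLF) solid-state NMR is the standard way to
measure C–H bond order parameters |S<sub>CH</sub>| in fluid lipid membranes
and other anisotropically mobile systems without isotope labelling: an
R18₁⁷ symmetry sequence applied on the protons under magic-angle spinning
(MAS) recouples the ¹H–¹³C dipolar interaction during the indirect
dimension, and the splitting Δν of the resulting Pake-like dipolar
lineshape gives

&nbsp;&nbsp;&nbsp;&nbsp;|S<sub>CH</sub>| = Δν / (κ·d<sub>CH</sub>),&nbsp;&nbsp;
κ = 0.315 (R18₁⁷),&nbsp; d<sub>CH</sub> ≈ 22 kHz.

For complex samples (lipid extracts, membranes with many components) only
a handful of indirect-dimension points can be afforded, the splitting is
not resolved, and the dipolar modulation s(t₁) must be **fitted** in the
time domain instead.  The catch is that R-symmetry recoupling is very
sensitive to the radio-frequency (B₁) field, which is spatially
inhomogeneous across the coil: the measured signal is a sum over sample
volumes with different local RF scales.  Fitting with an ideal
(homogeneous-RF) model then biases the extracted order parameters, while a
model that integrates the simulations over the measured RF distribution
fits the data accurately.

`rpdlf` implements this whole analysis chain:

* **spin dynamics** — two-spin (¹H–¹³C) density-matrix propagation through
  the R18₁⁷ schedule (18 π-pulse elements per rotor period, phases ±70°,
  ν₁ = 9 × MAS rate) with ZCW-style powder averaging, in compiled code;
* **RF inhomogeneity** — Gaussian or tabulated distributions of the
  relative nutation frequency, integration of the simulations over the
  profile, and a nutation-based estimator of the profile;
* **modulation databases** — pre-simulated curves over a grid of
  |S<sub>CH</sub>| values, interpolated continuously during fitting;
* **time-domain fitting** — deterministic global χ² minimization for one
  or two components with an exponential damping parameter and
  profile-likelihood confidence bounds;
* **frequency-domain utilities** — cosine-transform dipolar spectra,
  splitting read-off, conversions for ¹H–¹³C dipolar and ²H quadrupolar
  (126 kHz) couplings, and the minimum acquisition length needed to
  resolve two close splittings;
* **synthetic data** — a seeded generator for multi-component,
  inhomogeneity-weighted, damped, noisy modulations.

## Worked example

```r
library(rpdlf)

## ideal R-PDLF simulation: read the splitting off the dipolar spectrum
cond <- simulation_conditions(s_ch = 0.10, mas_rate = 5000)
mod  <- simulate_modulation(cond, n_points = 256)
dnu  <- read_off_splitting(dipolar_spectrum(mod))
sprintf("splitting = %.1f Hz, |S_CH| = %.4f", dnu, splitting_to_sch(dnu))
#> "splitting = 683.6 Hz, |S_CH| = 0.0986"
```

The read-off recovers the input |S<sub>CH</sub>| = 0.10 to ~1.4%; the
residual deviation is the finite-acquisition truncation bias of the horn
position (it shrinks as the acquisition lengthens).

```r
## realistic two-component dataset (0.03/0.04, RF inhomogeneity, 5% noise,
## 16 points) fitted with the inhomogeneity-aware database
db  <- build_database(seq(0, 0.15, by = 0.005),
                      simulation_conditions(s_ch = 0),
                      gaussian_rf_distribution(), n_points = 16)
dat <- generate_modulation(synth_spec(seed = 2))
fit <- confidence_bounds(dat, db, fit_components(dat, db, n_components = 2))
print(fit)
#> model: rf_inhomogeneous
#> n_components: 2
#> fractions: fixed-equal
#> n_points_used: 16
#> line_broadening_hz: 0 (free)
#> chi2: 0.033088019
#> component 1: |S_CH| = 0.0306  fraction = 0.500  [0.0185, 0.0492] @ 90%
#> component 2: |S_CH| = 0.0374  fraction = 0.500  [0.0185, 0.0492] @ 90%
#> database: ... rf=gaussian sigma=0.1 (rpdlf 0.1.0)
```

Both components are recovered close to their true values (0.03 and 0.04)
from only 16 points — an acquisition far too short to resolve the two
splittings in the frequency domain (that would need t₁ₘₐₓ ≥
`min_resolving_t1max(0.03, 0.04)` ≈ 7.2 ms, i.e. 36+ points at 5 kHz MAS).
The 90% bounds come from the profile likelihood; the wide interval
honestly reflects how close the two components are at this noise level.

A command-line interface wrapping the same functions (subcommands
`simulate`, `build-db`, `fit`, `convert`, `synth`) is installed at
`system.file("scripts", "rpdlf", package = "rpdlf")`.

## Package layout

* `R/`, `src/` — implementation (R surface, Rcpp propagation core)
* `tests/testthat/` — unit, property and end-to-end tests
* `vignettes/rpdlf-methods.Rmd` — the model, its assumptions, numerical
  choices and limitations
* `scripts/acceptance.R` — headline-quantity reproduction script
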