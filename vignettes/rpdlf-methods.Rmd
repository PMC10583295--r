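---
title: "Models and methods behind rpdlf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rpdlf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rpdlf)
```

# The physical model

`rpdlf` simulates the indirect dimension of an R-PDLF experiment: a ¹H–¹³C
spin pair evolving under magic-angle spinning (MAS) while the R18₁⁷
symmetry sequence is applied on the proton channel.  The rotating-frame
Hamiltonian is

$$H(t) = \omega_d(t)\, 2I_zS_z
       + \omega_1 \left(I_x\cos\phi(t) + I_y\sin\phi(t)\right)
       + \Delta\omega\, I_z ,$$

with $I$ the proton and $S$ the carbon spin.  The dipolar coefficient is
evaluated geometrically: the coupling-tensor symmetry axis at crystallite
orientation $(\beta,\gamma)$ in the rotor frame is rotated into the
laboratory frame (rotor axis at the magic angle, phase $\omega_r t$) and

$$\omega_d(t)/2\pi = S_{CH}\, d_{CH}\, P_2(\cos\theta(t)),$$

where $d_{CH}$ = 22 kHz is the rigid one-bond coupling magnitude and
$S_{CH}$ the C–H bond order parameter.  All motional averaging is absorbed
into the product $S_{CH} d_{CH}$ of an axially symmetric effective tensor
(bilayer-normal symmetry axis); no explicit dynamics are simulated, and
only the magnitude $|S_{CH}|$ is determined.  A multilamellar-vesicle
sample is an isotropic powder of symmetry-axis orientations, which is what
the powder average represents.

Because the carbon is a passive spin ($[H, S_z] = 0$), the 4×4 problem
factorizes into two spin-1/2 blocks with effective fields
$(\omega_1\cos\phi,\ \omega_1\sin\phi,\ \Delta\omega \pm \omega_d(t))$.
The compiled core exploits this: each propagation sub-step is a closed-form
SO(3) rotation, the one-rotor-period block propagator is accumulated once
(the Hamiltonian is periodic with the rotor period), and the modulation at
$t_1 = k\,\tau_r$ follows from its matrix powers.  A dense 4×4
density-matrix propagator (`propagate()`) is kept as the slow, transparent
reference; the test suite checks the two agree to 1e-9 and that
propagation is unitary and trace-preserving.

## The R18₁⁷ schedule

One R18₁⁷ block spans exactly one rotor period and consists of 18 equal
elements, each a π rotation (nominal ν₁ = 9 × MAS rate, so ν₁·τ = 1/2)
with phases alternating ±70° (= π·7/18).  RF miscalibration is modelled by
scaling ν₁ while keeping the rotor-synchronized timing, as in a real
spectrometer where pulse widths are set by the spinning rate.  The
modulation is sampled at block boundaries, where the cyclic RF propagator
closes; one rotor period per t₁ increment matches how the experiment is
acquired.

**Phase-order symmetrization.**  The element phase pattern can equally
start with +70° or −70°; both are valid realizations of the same symmetry
cycle.  A single fixed ordering leaves a small O((Δω/ω₁)²) asymmetry
(~1e-4) between positive and negative proton offsets that survives even a
continuous γ average.  The package therefore averages the two orderings by
default (`symmetrize_phase = TRUE` in `simulate_modulation()`): one
ordering at offset +Δω is exactly equivalent to the other at −Δω, so the
average is machine-exactly invariant under the offset sign — the symmetry
the experiment obeys.  The effect on the modulation itself is below 1e-4
under ideal settings.  No supercycle is applied within a schedule; this is
signal-level averaging of two start conventions.

## Effective behaviour

At block boundaries a single crystallite follows the power of one
fixed-axis rotation, $s(k) = a + (1-a)\cos(2\pi f_{\mathrm{eff}} k\tau_r)$.
The effective frequency scales as $\sin^2\beta$ with maximum
$\kappa\,S_{CH}\,d_{CH}/2$, so the powder horns sit at peak-to-peak
splitting $\kappa\,S_{CH}\,d_{CH}$ with κ = 0.315 — the known scaling
factor of R18₁⁷, which the simulation reproduces rather than assumes (the
test suite reads it off a 512-point simulated spectrum to within 2%).  The
pedestal $a \approx n_z^2$ is a genuine second-order effect (the effective
rotation axis tilts out of the transverse plane by roughly
$(S_{CH}d_{CH}/\nu_1)/\kappa$); at $S_{CH} = 0.1$ it reaches several
percent, which is why the trajectory oracle in the tests fits the full
rotation form rather than a bare cosine.

The horn position read off a finite acquisition converges to
$\kappa S_{CH} d_{CH}$ from below; truncating at four reciprocal
splittings leaves an error of roughly 10% (the acceptance script computes
≈13% under its exact read-off convention), which motivates time-domain
fitting whenever acquisitions are short.

# Powder averaging

The default scheme (`powder_orientations("zcw", 233)`) is a ZCW-style
golden-section spherical lattice: cos β stratified uniformly, γ advanced
by the golden angle, equal weights, n snapped to a Fibonacci number.  It
is deterministic, quasi-uniform, and reproduces the analytic spherical
average ⟨P₂(cos β)⟩ = 0 to ~1e-5 at n = 233 — ample for the smooth
Pake-like lineshapes involved.  A repulsion-relaxed variant and a
single-crystallite scheme are available.  233 orientations is a
convergence-tested choice: doubling it changes read-off and fit results
well below their tolerances.

# RF inhomogeneity

The B₁ field across the coil is represented by a discrete distribution of
the *relative* nutation frequency ν₁/ν₁(nominal).  The default
(`gaussian_rf_distribution()`) is a Gaussian with center 1.0 and σ = 0.10,
21 nodes over ±3σ: with this width the 2σ edge of the profile sits at 80%
of the nominal amplitude, the level typically quoted for the outer parts
of a solenoid MAS coil.  These are configuration values, never hard-coded
into results; when the actual coil profile has been measured (e.g. by the
nutation method, `estimate_rf_distribution()`), the measured parameters
should be used instead.  Detection-sensitivity weighting is assumed folded
into the weights — a single effective distribution.

Integrating the simulations over this distribution
(`integrate_over_rf()`) produces the two signatures the fitting model must
capture: damping of the oscillation, and a non-zero long-time average that
transforms into a central ("middle") spectral peak.  Both grow
monotonically with σ (property-tested over σ ∈ {0, 0.05, 0.1, 0.15}).

The nutation estimator Fourier-transforms a nutation decay, locates the
dominant band, and returns truncation-corrected Gaussian moments; the
tests verify it recovers a known generating width (σ = 0.08) within 15%
and that 5% additive noise moves the recovered center by under 1%.

# Modulation databases and fitting

Fitting never re-runs spin dynamics.  `build_database()` pre-computes one
(inhomogeneity-integrated) curve per order-parameter grid point; the
default grid for lipid work is s ∈ [0, 0.35] in steps of 0.005, and
curves are interpolated cubically in s during optimization (node-exact;
off-grid error vs direct simulation ~1e-3 at 16–32 points, property-tested
against direct simulations at random off-grid values).  Interpolation is
in the s dimension only: the t₁ grid is tied to the acquisition geometry,
and a database built with more points serves any acquisition whose grid is
a prefix of it.  Databases serialize to a single full-precision JSON
document (lossless round-trip to 1e-12, human-inspectable).

`fit_components()` minimizes the unweighted χ² of

$$\textstyle\sum_i f_i\, m(s_i; t_1)\, e^{-\pi\,\mathrm{lb}\,t_1}$$

over one or two components.  Conventions and choices:

* **Damping.**  The exponential multiplier uses the Lorentzian
  full-width convention exp(−π·lb·t₁); lb is free by default (bounded at
  100 Hz), or can be fixed.  Mismatched models absorb unmodelled decay
  into lb — fitting inhomogeneity-generated data with the ideal model
  inflates lb far above the matched-model value, a property-tested
  diagnostic of model inadequacy.
* **Fractions.**  Equal by default (the minimal-parameter assumption,
  appropriate for chemically near-equivalent sites such as the two acyl
  chains of a phospholipid); a free-fraction mode exists.
* **Optimization.**  Exhaustive scan over the database grid (all pairs
  for two components) with an inner golden-section line search over lb,
  followed by a bounded L-BFGS-B polish on the interpolated surface.
  χ² surfaces of beat-type problems are multimodal; the deterministic
  global scan avoids both random restarts and silent local minima.
  Ties resolve to the smallest total s, then smallest lb.
* **Confidence bounds.**  `confidence_bounds()` profiles each component:
  the 90% interval (F(1, n−p) scaling of χ²_min) is found by re-optimizing
  the remaining parameters at fixed s and locating the threshold crossing
  by root-finding.  Intervals hitting the grid edge are flagged.  This is
  a standard, declared convention; noiseless self-fits collapse to
  intervals narrower than one grid step, and widths grow with noise
  (both property-tested).

**A finding on two-component protocols.**  On short, noisy two-component
fixtures (e.g. 0.03/0.04 on 16 points with 5% noise) the pair is
statistically near-degenerate — the acquisition is shorter than the
half-beat resolution time — so equal-fraction estimates scatter along a
χ² valley and often collapse toward their mean, while remaining within
±0.007 of the truth.  Fitting the same inhomogeneity-generated data with
the *ideal* model under the equal-fraction protocol does not produce a
grossly overestimated large component at the global minimum: instead the
global solution collapses the small component toward a flat (s ≈ 0) curve
to mimic the raised long-time baseline.  The dramatic overestimation
failure mode (larger component inflated by factors of ~2) appears when
component amplitudes are left free: the fit then buys the inhomogeneity
damping with a small-weight, fast-decaying large-s component.  Both
failure modes demonstrate the same point — the ideal model is the wrong
model for inhomogeneous data — but which one a fit lands in depends on the
protocol and, near degeneracy, on the individual noise realization.

# The synthetic-data generator

`synth_spec()`/`generate_modulation()` produce the package's test fixture:
a fraction-weighted sum of inhomogeneity-integrated modulations,
exponentially damped, with i.i.d. Gaussian noise added to the t₁ > 0
points (the t₁ = 0 point is the normalization reference and carries no
noise; experimental s(0) is the normalization denominator).  Defaults:
equal components at 0.03 and 0.04, the default Gaussian RF profile, no
extra damping, noise σ = 0.05 of s(0), 16 points at 5 kHz MAS.  Generation
is seeded and bit-reproducible, and the generator shares no code path with
the fitting databases beyond the simulation core itself (data are
integrated directly, fits interpolate a pre-built grid).

What it does **not** emulate: rINEPT transfer-efficiency weighting between
components, ¹H–¹H residual couplings, t₁-noise or spectrometer artifacts,
B₀ inhomogeneity, and the direct (¹³C shift) dimension.  Passing tests
therefore show correctness of the analysis chain under the stated model,
not robustness to every feature of real spectrometer data.

`generate_two_pake_superposition()` is a separate analytic illustration of
the two-splitting resolution limit (`min_resolving_t1max()`, the half beat
period 1/(2κ d |s₂−s₁|)): equal-weight first-order powder modulations with
no RF effects, on arbitrary time grids.

# Numerical choices

* **Sub-steps**: 32 per R element (piecewise-constant Hamiltonian at the
  element-midpoint rotor phase).  Halving the step changes the modulation
  by < 1e-4, the package's step-convergence requirement.
* **Spectra**: real cosine transform with half-weighted first point,
  zero-fill ×8 by default, no apodization for read-off (apodization biases
  horn positions).  Horn picking excludes |f| below 1.5 pre-zero-fill bins
  (the middle peak) and candidates below 15% of the global maximum
  (truncation ringing; the first positive boxcar sidelobe is ~13%).
* **Degenerate inputs**: zero coupling and zero RF both yield flat
  modulations (verified); σ = 0 RF distributions degenerate to deltas;
  equal order parameters are rejected where a beat period is required.
* **Problem sizes in the tests**: unit tests run an 89-orientation powder
  with reduced RF node counts; the end-to-end tests and the acceptance
  script use the full study conditions (233 orientations, 21 RF nodes,
  71-point s grid) — sizes chosen as the smallest that leave all checked
  quantities converged well inside their tolerances.

# Known limitations

* Single ¹H–¹³C pair: multi-proton effects (R18₁⁷ decouples ¹H–¹H only to
  first order) are outside the model.
* Coherent dynamics only; relaxation enters solely as the phenomenological
  exponential damping of the fits.
* Only |S_CH| is determined; the sign of the order parameter is not.
* Databases fix offset and miscalibration per database; no joint gridding
  of offset × RF scale × s.
* The ideal-vs-inhomogeneous model comparison assumes the RF distribution
  used for generation/fitting is the true coil profile; with a measured
  profile of the wrong shape the "matched" model is itself misspecified.
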