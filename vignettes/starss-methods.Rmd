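---
title: "STARSS models and methods: photoswitching, rotational diffusion, and anisotropy recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{STARSS models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starss)
```

## The physical model

A fluorophore is a point dipole with orientation $\Omega$ on the unit
sphere, carrying one of a small set of molecular states: fluorescent
**ON**, dark **OFF**, an optional dark ground-state **INTERMEDIATE**, and
an optional irreversibly **BLEACHED** sink. The state densities
$n_s(\Omega, t)$ obey orientation-resolved rate equations coupled to
rotational diffusion,

$$
\partial_t n_s = D_r \, \Delta_{S^2} n_s + \sum_{s'} K_{ss'}(\Omega)\, n_{s'},
$$

where $\Delta_{S^2}$ is the spherical Laplacian and every light-driven
rate follows the one-photon photoselection law: for linear polarization
along $\hat e$, $k(\Omega) = k_\text{peak} P \,(\hat\mu\cdot\hat e)^2$;
for circular polarization in the plane perpendicular to the optical axis
$\hat z$, $k(\Omega) = k_\text{peak} P \,(1 - \mu_z^2)/2$, with $P$ the
power density. 405-nm light drives OFF→ON only; 488-nm probe light
simultaneously excites fluorescence and drives ON→OFF (optionally through
the intermediate). Detected flux in the two analyzer channels ($\hat x$
"parallel", $\hat y$ "perpendicular") weights the emission dipole by
$\tfrac32\langle(\hat\mu_\text{em}\cdot\hat e_\text{det})^2\rangle$,
azimuthally averaged over the absorption–emission dipole cone when
`dipole_angle_abs_em` is nonzero. The normalization is fixed so that an
isotropic ON population splits equally between the channels ($r = 0$
exactly) and a fresh $\cos^2$-photoselected population with collinear
dipoles emits at the classical ceiling $r_0 = 0.4$; both identities are
enforced by tests.

Assumptions worth stating explicitly:

* **Point-dipole, low-NA detection.** High-NA depolarization and
  vectorial collection are ignored; the two analyzers see
  $\propto \mu_x^2$ and $\propto \mu_y^2$. This is the standard idealized
  TR-FA detection model; static reference samples then show flat curves,
  which is the behaviour the method relies on.
* **Linear brightness.** Detected photons per excitation are a constant
  (`brightness`), so expected counts scale linearly with power, cycle
  count and population — the basis of the tenfold method-2 yield
  argument.
* **Isotropic rigid rotor.** A single $D_r$ (or a static/mobile
  two-component mixture via `static_fraction`); no anisotropic diffusion
  tensors, no local wobble-in-cone modes. Stretched-exponential decays
  are fitted as a phenomenological description of heterogeneous size
  distributions, not derived from a microscopic model.
* **Cycle accumulation assumes complete reset.** Expected counts are
  multiplied by `cycles`; the trailing OFF-switching reset segment is
  simulated, and its completeness is the user's responsibility (the
  defaults reach $e^{-20}$ residual ON population for rotors faster than
  the reset window; a perfectly static sample retains a small ON
  population at the circular-reset poles).

## One scheme, three observables

All three pulse schemes are programs over the same engine
(`scheme_segment`/`pulse_scheme`), differing only in which transition is
photoselected and what is detected:

* **Method 1** (OFF→ON photoselection, circular probe): the probe is
  symmetric about $z$, so it reads the photoselected $x$-alignment
  without adding its own in-plane bias; $r(t)$ decays as
  $\exp(-6 D_r t) = \exp(-t/\tau_\text{rot})$ up to probe-depletion
  corrections, which at the default probe fluence keep even a static
  sample's drift below 0.02.
* **Method 2** (ON→OFF photoselection, linear probe): the probe silences
  aligned molecules; anisotropy decays when OFF-switching wins and is
  stationary when rotation wins. Quantitative fitting of method-2 curves
  is provided only closed-loop against this package's own forward model
  — the shapes depend on the full competition and do not reduce to the
  conventional TR-FA expression.
* **Method 3** (pulse-pair ON-switching, delayed): the observable is the
  *total* probed signal versus pulse delay, normalized by a matched
  single-pulse reference simulated with the same settings. By default
  detection is unpolarized (a single photodiode suffices for this
  scheme); a polarization-resolved mode is retained as an option for
  setups that record the analyzer channels anyway. With unpolarized
  detection the degenerate limits are exact: a zero-fluence second pulse
  gives normalized counts of 1 at every delay, and a static rotor gives
  a delay-independent curve.

The method-3 delay curve is inverted by fitting the saturating recovery
$F(\Delta) = F_\infty - (F_\infty - F_0) e^{-\Delta/\tau_\text{eff}}$ and
mapping $\tau_\text{eff} \to \tau_\text{rot}$ through a lookup computed
from the forward simulator itself (`method3_calibration`, cached). The
mapping is close to, but not exactly, the identity: saturated
photoselection populates $l = 4$ orientational modes that relax at
$20 D_r$ rather than $6 D_r$, biasing $\tau_\text{eff}$ low; the
calibration absorbs this.

## Numerics

* **Grid.** Gauss–Legendre nodes in $\cos\theta$ × uniform azimuth
  (default 64 × 128). Quadrature of the polynomial kernels is exact;
  dipole component matrices and associated-Legendre tables are cached
  per resolution.
* **Diffusion.** Exact spectral propagation: azimuthal FFT, then a
  precomputed sparse block-diagonal propagator
  $P_m\,\mathrm{diag}(e^{-l(l+1)D_r\,dt})\,P_m^{\mathsf T}W$ per
  azimuthal order, cached per $(grid, D_r\,dt)$. Unconditionally stable;
  the uniform field is an exact fixed point, mass is conserved to
  machine precision, and the $P_2$ eigenmode decays as
  $e^{-6 D_r t}$ to ~1e-13 (tested against an independent
  finite-difference propagation). The band limit defaults to
  $l_{\max} = \min(n_\theta - 1, 40)$: the populations are products of
  smooth saturation profiles whose spectra die off far below that, and
  the truncation acts only as a mild smoother.
* **Reactions.** Within a step the rates are constant, so the per-cell
  kinetics (including the intermediate chain and bleaching) are solved
  in closed form, and the emitted photons are the exact time integral of
  the ON population against the excitation kernel over the step — no
  reaction-substep error, only splitting error.
* **Splitting.** Merged Strang composition per segment:
  $D(dt/2)\,[R(dt)\,D(dt)]^{n-1}R(dt)\,D(dt/2)$, with the sub-step
  chosen so $\max(\text{rate})\,dt \le 0.1$ during probing. 405-nm
  pulse segments use a coarse sub-step: their reaction update is exact
  at any $dt$ and rotation over 50–250 ns is negligible for every rotor
  in the method's range, so fine splitting there buys nothing. Reset
  segments are likewise coarse; only their depletion end point matters.
  The probe path is validated against an independent Legendre-mode ODE
  oracle (deSolve) to better than $10^{-3}$ relative on emitted fluxes.
* **Fitting.** The monoexponential fit profiles $\tau$ on a log grid
  spanning the observation window (linear weighted least squares for the
  offset and amplitude at each $\tau$, golden-section refinement), which
  is deterministic and needs no starting guesses. Weights are
  $1/\mathrm{CI}^2$ from the delta-method propagation of Poisson
  variance. Model selection against the constant-only fit uses AICc; a
  curve the constant model explains at least as well returns
  `tau = NA` flagged unconstrained rather than a fabricated number, and
  a $\tau$ pinned at the profile-grid boundary is treated the same way.
  The stretched-exponential fit uses Levenberg–Marquardt
  (`minpack.lm`) from several $\beta$ starts with bounds
  $\beta \in [0.05, 1]$; a $\beta$ at a bound is flagged. Diameter
  intervals transform the $\tau$ interval endpoints through the
  cube-root Stokes–Einstein–Debye relation (asymmetric by construction).
* **Degenerate inputs.** Bins whose corrected denominator is not
  positive are flagged invalid and excluded from fits with a logged
  count, never silently dropped; zero-count bins report undefined
  intervals; background-only records yield all-invalid curves rather
  than NaNs.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `temperature`, `viscosity` | K, Pa·s | 293, 1e-3 | water at room temperature; the condition under which sizes are quoted |
| `k_on_peak` | 1/s per W/cm² | 2000 (rsEGFP2 preset) | puts sub-µs ON-switching at kW/cm² 405 nm |
| `k_off_peak` | 1/s per W/cm² | 12 | puts 0.1–1 ms OFF-switching at kW/cm² 488 nm, the tunable probe window |
| `intermediate_rate` | 1/s | 2e4, disabled | 50-µs ground-state intermediate of the high-power regime; enabling it makes OFF-switching bi-exponential |
| `on_fraction` (method 1) | – | 0.10 | small enough that the OFF pool stays nearly isotropic; calibrated by root-finding on the saturable photoselection integral |
| `on_fraction_first` (method 3) | – | 0.50 | the modulation-depth optimum (the package's own sweep reproduces it) |
| `g_factor` | – | 1 | detector gain ratio; calibrate with `calibrate_g()` on an isotropic record |
| `bin_width` | s | 2e-6 | resolves tens-of-µs decays over a 1-ms probe; lower it toward the 10-ns hardware floor for small, fast rotors |

The shipped fluorophore presets are order-of-magnitude defaults (flagged
as such in their JSON `provenance` fields): they set realistic time
scales so that the *relative* claims — decay-rate ratios, yield ratios,
modulation optima, recovery accuracy — are meaningful. None of the
absolute photon numbers should be read as instrument predictions.

## What the synthetic data do and do not emulate

The generator (`generate_fixture`, and the samplers inside the
simulators) reproduces: cos²-law photoselection with saturation,
the competition of switching and rotation, bin-level Poisson shot noise,
detector gain imbalance, cross-talk background and dark counts as
independent Poisson streams, static/mobile mixtures, and image-mode
records with region structure and per-pixel sampling. Scenario presets
cover rigid beads (30/60/100 nm), an immature/mature particle contrast
(slow constrained rotor with a large static fraction versus a fast free
one), a bright-cluster/cytosol field with 22.2 µs and 8.1 µs correlation
times, and a static reference.

Not emulated: detector dead time and afterpulsing, scanning and timing
jitter, high-NA depolarization, homo-FRET between crowded labels,
anisotropic or hindered rotation, photophysical blinking beyond the
single dark intermediate, and sample drift. Passing the recovery tests
therefore demonstrates the *estimator chain* is correct and well
calibrated under the stated noise model — not that real instruments are
free of these additional effects.

## Problem sizes

The test suite and the acceptance script run the engine at 32 × 64 and
64 × 128 orientation grids respectively; recovery studies use 10⁶–10⁷
photon budgets over 500–1000 time bins, five-seed repeats for noisy
recoveries, and a 37-point fluence sweep for the modulation optimum.
These sizes were chosen so the full suite completes in a few minutes on
one CPU while every tolerance retains a comfortable margin; results are
insensitive to the grid beyond 32 × 64 because the fields involved are
spectrally narrow.

## Known limitations

* Method-2 curves are quantified only against this package's own
  forward model; no closed-form likelihood is provided.
* The mass of a complex is deliberately not derived from its diameter:
  mass–size scaling depends on shape and packing assumptions the model
  does not make.
* The eight-state description of rsFP photophysics is represented here
  by the orientation-resolved ON/OFF(/INTERMEDIATE/BLEACHED) kinetics;
  the state set is configurable, but no claim of algebraic identity
  with any specific published state graph is made.
* `cycles` multiplies expectations; cycle-to-cycle memory (incomplete
  reset, accumulating bleach) is not simulated.
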