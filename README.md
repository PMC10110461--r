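# starss

Selective time-resolved fluorescence anisotropy with reversibly switchable
states (STARSS), as a self-contained simulation and analysis toolkit in R.

## The problem

Time-resolved fluorescence anisotropy (TR-FA) measures how fast a labelled
molecule tumbles: polarized light photoselects molecules whose transition
dipole is aligned with the field, and the anisotropy

```
r = (I_par − G · I_perp) / (I_par + 2 G · I_perp)
```

of the emitted light decays as the orientations randomize, with the
rotational correlation time `tau_rot = 1/(6 D_r)`. For a rigid sphere the
Stokes–Einstein–Debye relation links that time to the hydrodynamic volume,

```
tau_rot = eta · V_h / (k_B · T),   V_h = (pi/6) · d³,
```

so `tau_rot` is a direct size readout. Conventional TR-FA only watches
orientation for the few nanoseconds of the fluorescence lifetime, which
caps the observable size at a few tens of kDa. Reversibly switchable
fluorescent proteins (rsFPs, e.g. rsEGFP2 or DronpaM159T) evade that cap:
their ON and OFF states are long-lived (microseconds to minutes), so
photoselection applied to the *switching* transitions marks an oriented
subpopulation whose orientation can be probed for milliseconds —
extending the accessible range from a ~5-nm GFP (`tau_rot` ≈ 16 ns in
water) to particles of 100 nm and beyond (`tau_rot` ≈ 130 µs).

The package implements the three pulse schemes built on this idea and the
full analysis pipeline around them:

* **Method 1** — a short linearly polarized 405-nm pulse switches ~10% of
  molecules ON (photoselection on OFF→ON); circularly polarized 488-nm
  light reads their polarized fluorescence while slowly switching them
  back OFF. Nearly classical TR-FA, on a millisecond clock.
* **Method 2** — all molecules start ON; a linearly polarized 488-nm
  probe simultaneously excites and OFF-switches aligned molecules
  (photoselection on ON→OFF). Anisotropy decays when OFF-switching
  outcompetes rotation, and is stationary when rotation is faster;
  starting from 100% ON yields ~10× more photons per cycle than the 10%
  preset of method 1.
* **Method 3** — two identical linearly polarized ~50-ns 405-nm pulses
  separated by a variable delay (0.2–500 µs), followed by an unpolarized
  readout. If the OFF pool rotates during the delay, the second pulse
  finds fresh aligned molecules and the total signal grows with delay;
  the modulation is deepest when the first pulse switches ~50% ON.

Under the hood sits an orientation-resolved kinetic engine: molecular
state populations (ON, OFF, optional dark intermediate, bleached) live on
a Gauss–Legendre × FFT grid over the orientation sphere; light-driven
transitions follow the cos² one-photon photoselection law, and rotational
diffusion is propagated spectrally (each spherical-harmonic mode damped
by `exp(−l(l+1) D_r dt)`), which is unconditionally stable and exact to
the band limit. The analysis side provides anisotropy estimation with
delta-method or bootstrap confidence intervals, G-factor calibration,
cross-talk background estimation from the reset window, mono- and
stretched-exponential decay fits with size conversion, the method-3
delay-curve inversion, intensity-threshold image segmentation,
per-region decays and per-pixel anisotropy maps.

## Worked example

Simulate a method-1 measurement of a 60-nm particle in water at a
10⁷-photon budget with a slightly unbalanced detector, then run the
standard analysis chain (background from the reset window, G-corrected
anisotropy, weighted monoexponential fit, size inversion):

```r
library(starss)
env   <- environment_params(temperature = 293, viscosity = 1e-3)  # water
fluor <- fluorophore_preset("rsEGFP2")
rotor <- rotor_model(diameter = 60e-9, env = env)    # a 60-nm particle

cur <- simulate_method1(fluor, rotor, detector = detector_pair(g_factor = 1.1),
                        grid = sphere_grid(48, 96), bin_width = 2e-6,
                        target_photons = 1e7, seed = 1)
bg  <- estimate_background(cur)
an  <- compute_anisotropy(cur, G = 1.1, background = bg,
                          use_segments = "probe")
fit <- fit_monoexponential(an, env = env)
print(fit)
```

```
<starss_fit> monoexp_static
  r_static = -0.0005184, A = 0.3714, tau = 2.871e-05 s (se 1.7e-07)
  diameter = 60.5 nm (95% CI 60.3--60.8)
  AICc 471.3 (constant: 1.2e+05), 500 bins
```

Reading the output: the anisotropy starts near the photoselection limit
(`r_static + A ≈ 0.37`, just below the theoretical 0.4 because of the
mild saturation of the 10% ON pulse) and decays with
`tau = 28.7 µs` — the Stokes–Einstein–Debye time of a 60-nm sphere in
water is 28.0 µs — giving a fitted hydrodynamic diameter of 60.5 nm with
a sub-nanometre confidence interval at this photon budget. The huge AICc
gap to the constant model says the decay is decisively resolved; a truly
static sample would instead return `tau` flagged as unconstrained.

A thin command-line layer exposes the same pipeline
(`simulate`, `fit`, `map`, `calibrate-g`, `fixtures`):

```sh
Rscript inst/cli/starss.R simulate --scheme method1 --diameter-nm 100 --seed 1 --out run1
Rscript inst/cli/starss.R fit --input run1_decay.csv --model monoexp
```

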