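Package: starss
Title: Selective Time-Resolved Anisotropy with Reversibly Switchable States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and analysis of selective time-resolved
    fluorescence anisotropy with reversibly switchable fluorescent proteins
    (STARSS). Provides an orientation-resolved kinetic engine for polarized
    photoswitching coupled to rotational diffusion on the sphere, simulators
    for the three STARSS pulse schemes, anisotropy estimation with
    confidence intervals, mono- and stretched-exponential decay fitting,
    Stokes-Einstein-Debye hydrodynamic size inversion, intensity-based
    image segmentation with per-region decays and per-pixel anisotropy
    maps, and a synthetic fixture generator so that rotational diffusion of
    objects from ~5 nm to ~100 nm hydrodynamic diameter can be simulated,
    fitted and recovered without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    Matrix,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    tiff,
    pracma,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
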