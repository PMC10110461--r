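{
  "name": "rsEGFP2",
  "k_on_peak": 2000,
  "k_off_peak": 12,
  "k_exc_peak": 20000,
  "brightness": 0.05,
  "dipole_angle_abs_em": 0,
  "intermediate_rate": 20000,
  "bleach_rate": 0,
  "provenance": "order-of-magnitude defaults for a fast-switching rsFP; time scales (sub-us ON-switching at kW/cm^2 405 nm, 0.1-1 ms OFF-switching at kW/cm^2 488 nm, ~50 us ground-state intermediate in the high-power regime) are representative, the individual constants are not fitted measurements",
  "units": {
    "k_on_peak": "1/s per W/cm^2 at 405 nm, dipole parallel to field",
    "k_off_peak": "1/s per W/cm^2 at 488 nm, dipole parallel to field",
    "k_exc_peak": "1/s per W/cm^2 at 488 nm, dipole parallel to field",
    "intermediate_rate": "1/s",
    "dipole_angle_abs_em": "radians"
  }
}
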