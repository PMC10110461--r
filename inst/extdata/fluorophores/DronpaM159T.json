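{
  "name": "DronpaM159T",
  "k_on_peak": 1000,
  "k_off_peak": 8,
  "k_exc_peak": 15000,
  "brightness": 0.04,
  "dipole_angle_abs_em": 0,
  "intermediate_rate": 20000,
  "bleach_rate": 0,
  "provenance": "order-of-magnitude defaults for a fast-switching rsFP, slightly slower switching than the rsEGFP2 preset; not fitted measurements",
  "units": {
    "k_on_peak": "1/s per W/cm^2 at 405 nm, dipole parallel to field",
    "k_off_peak": "1/s per W/cm^2 at 488 nm, dipole parallel to field",
    "k_exc_peak": "1/s per W/cm^2 at 488 nm, dipole parallel to field",
    "intermediate_rate": "1/s",
    "dipole_angle_abs_em": "radians"
  }
}
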