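{
  "version": "1.0",
  "system": "vitamin B12 (cobalamin) in Tb-mesoMOF single crystals",
  "max_load_ratio": {
    "value": 0.33,
    "units": "mg guest per mg MOF",
    "note": "literature-reported maximum vitamin B12 load per mg Tb-mesoMOF; defines the ceiling of a colorimetric detection range"
  },
  "initial_uptake_rate": {
    "value": 0.112,
    "units": "fraction of saturation per hour",
    "note": "literature-reported total initial uptake rate; the early uptake is close to linear, so short measurements approximate it well"
  },
  "detection_limit": {
    "value": 10,
    "units": "ng/mL",
    "note": "literature-reported detection limit of absorption-spectroscopy quantification of vitamin B12"
  },
  "cage_diameters": {
    "value": [3.9, 4.7],
    "units": "nm",
    "note": "the two mesoporous cage types of Tb-mesoMOF"
  },
  "window_diameters": {
    "value": [1.3, 1.7],
    "units": "nm",
    "note": "apertures interconnecting the cages"
  },
  "molecule_dims": {
    "value": [1.83, 1.41, 1.14],
    "units": "nm",
    "note": "rigid-box dimensions of the vitamin B12 molecule, sorted descending"
  }
}
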