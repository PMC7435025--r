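{
  "name": "testing",
  "dims": [
    64,
    64
  ],
  "n_frames": 40,
  "dt": 1.0,
  "snr": 20,
  "voxels_per_dataset": null,
  "rng_seed": 20200820,
  "base_median_perfusion": 58,
  "sdlog_voxel": 0.45,
  "sdlog_dataset": 0.1,
  "sdlog_region": 0.1,
  "region_factors": [
    1.35,
    1.0,
    0.6
  ],
  "subject_factors": {
    "young_healthy": 1.0,
    "elderly_healthy": 0.75,
    "pad": 0.55
  },
  "load_factors": {
    "4lb": 1.0,
    "8lb": 1.6,
    "16lb": 2.6,
    "exhaustion": 3.2
  },
  "groups": [
    {
      "subject_type": "young_healthy",
      "n_subjects": 1,
      "loads": [
        "4lb",
        "8lb",
        "16lb",
        "exhaustion"
      ]
    },
    {
      "subject_type": "elderly_healthy",
      "n_subjects": 1,
      "loads": [
        "4lb",
        "exhaustion"
      ]
    },
    {
      "subject_type": "pad",
      "n_subjects": 1,
      "loads": [
        "4lb",
        "exhaustion"
      ]
    }
  ],
  "regions": [
    {
      "center_row": 0.32,
      "center_col": 0.3,
      "radius_row": 0.27,
      "radius_col": 0.23
    },
    {
      "center_row": 0.32,
      "center_col": 0.72,
      "radius_row": 0.27,
      "radius_col": 0.23
    },
    {
      "center_row": 0.72,
      "center_col": 0.5,
      "radius_row": 0.23,
      "radius_col": 0.36
    }
  ],
  "nuisance": {
    "t0": [
      1.5,
      6.5
    ],
    "minTT": [
      3,
      10
    ],
    "E": [
      0.2,
      0.6
    ],
    "k": [
      0.05,
      0.3
    ]
  },
  "aif": {
    "amplitude": [
      5,
      8
    ],
    "arrival": [
      1,
      3
    ],
    "alpha": [
      2.5,
      4
    ],
    "beta": [
      1.5,
      2.8
    ],
    "recirculation_fraction": [
      0.1,
      0.25
    ],
    "recirculation_tau": 12,
    "cof_base": 0.7,
    "cof_slope": 0.45,
    "cof_sdlog": 0.08
  },
  "perfusion_clip": [
    2,
    590
  ]
}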