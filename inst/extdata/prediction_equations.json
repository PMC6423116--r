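{
  "version": "1.0.0",
  "predictors": ["pw", "br", "apl", "ly", "epr"],
  "equations": {
    "j_max": {
      "response": "j_max",
      "transform": "log10",
      "coefficients": {
        "pw": 1.598,
        "br": -48.694,
        "apl": 0.016,
        "ly": -9.188,
        "epr": 52.705
      },
      "intercept": -4.874,
      "n_factors": 4,
      "vip_above_0.8": ["apl", "ly"],
      "r2y_published": 89.65
    },
    "j_r": {
      "response": "j_r",
      "transform": "log10",
      "coefficients": {
        "pw": 0.95,
        "br": -29.975,
        "apl": 0.005,
        "ly": -6.651,
        "epr": 3.072
      },
      "intercept": -2.905,
      "n_factors": 3,
      "vip_above_0.8": ["apl", "ly"],
      "r2y_published": 81.56
    },
    "j_el": {
      "response": "j_el",
      "transform": "identity",
      "coefficients": {
        "pw": -33.843,
        "br": 689.778,
        "apl": -0.265,
        "ly": 72.428,
        "epr": -1591.011
      },
      "intercept": 132.938,
      "n_factors": 4,
      "vip_above_0.8": ["pw", "br", "apl", "ly", "epr"],
      "r2y_published": 71.85
    },
    "eta0": {
      "response": "eta0",
      "transform": "log10",
      "coefficients": {
        "pw": -1.567,
        "br": 57.529,
        "apl": -0.018,
        "ly": 11.776,
        "epr": -54.449
      },
      "intercept": 6.519,
      "n_factors": 4,
      "vip_above_0.8": ["apl", "ly"],
      "r2y_published": 89.68
    },
    "g_star": {
      "response": "g_star",
      "transform": "reciprocal",
      "coefficients": {
        "pw": 9.275e-05,
        "br": -0.002446,
        "apl": 8.503e-07,
        "ly": -0.0004547,
        "epr": 0.003391
      },
      "intercept": -8.588e-05,
      "n_factors": 5,
      "vip_above_0.8": ["br", "ly"],
      "r2y_published": 84.26
    },
    "tan_delta": {
      "response": "tan_delta",
      "transform": "identity",
      "coefficients": {
        "pw": 0.151,
        "br": -4.067,
        "apl": 0.0007868,
        "ly": -1.01,
        "epr": 1.501
      },
      "intercept": 0.377,
      "n_factors": 3,
      "vip_above_0.8": ["apl", "ly"],
      "r2y_published": 84.83
    },
    "a_f": {
      "response": "a_f",
      "transform": "reciprocal",
      "coefficients": {
        "pw": 9.161e-05,
        "br": -0.002491,
        "apl": 8.597e-07,
        "ly": -0.0004586,
        "epr": 0.003489
      },
      "intercept": -8.525e-05,
      "n_factors": 5,
      "vip_above_0.8": ["pw", "br", "ly"],
      "r2y_published": 83.81
    },
    "z": {
      "response": "z",
      "transform": "identity",
      "coefficients": {
        "pw": 2.222,
        "br": 81.507,
        "apl": -0.005997,
        "ly": 13.389,
        "epr": -29.568
      },
      "intercept": -5.274,
      "n_factors": 4,
      "vip_above_0.8": ["apl", "ly"],
      "r2y_published": 83.26
    }
  }
}
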