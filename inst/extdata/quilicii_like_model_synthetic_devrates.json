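{
  "stages": {
    "egg": {
      "dev_rate": {
        "form": "briere1",
        "params": {
          "a": 0.000275,
          "Tmin": 5,
          "Tmax": 35
        }
      },
      "devtime_slope": 8,
      "mortality": {
        "form": "mortality_expquad",
        "params": {
          "b1": 5.183,
          "b2": -0.422,
          "b3": 0.009
        },
        "scale": "percent"
      }
    },
    "larva": {
      "dev_rate": {
        "form": "briere1",
        "params": {
          "a": 6.95e-05,
          "Tmin": 5,
          "Tmax": 35
        }
      },
      "devtime_slope": 8,
      "mortality": {
        "form": "mortality_expquad",
        "params": {
          "b1": 4.812,
          "b2": -0.29,
          "b3": 0.007
        },
        "scale": "percent"
      }
    },
    "pupa": {
      "dev_rate": {
        "form": "briere1",
        "params": {
          "a": 5.31e-05,
          "Tmin": 5,
          "Tmax": 35
        }
      },
      "devtime_slope": 8,
      "mortality": {
        "form": "mortality_expquad",
        "params": {
          "b1": 5.8716,
          "b2": 0.3892,
          "b3": 141.781
        },
        "scale": "percent"
      }
    }
  },
  "female_senescence": {
    "form": "senescence_exponential",
    "params": {
      "b1": 0.0061,
      "b2": 0.056
    }
  },
  "male_senescence": {
    "form": "senescence_exponential",
    "params": {
      "b1": 0.0058,
      "b2": 0.0624
    }
  },
  "fecundity": {
    "form": "fecundity_gaussian",
    "params": {
      "y0": -41393.36,
      "a": 41971.86,
      "b": 74.63,
      "x0": 25.126
    }
  },
  "oviposition": {
    "form": "ovip_gamma",
    "params": {
      "a": 3.404,
      "b": 3.906
    }
  },
  "female_ratio": 0.5,
  "adult_slope": "Inf"
}
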