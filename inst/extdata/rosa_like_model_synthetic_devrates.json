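{
  "stages": {
    "egg": {
      "dev_rate": {
        "form": "briere1",
        "params": {
          "a": 0.000322,
          "Tmin": 10,
          "Tmax": 38
        }
      },
      "devtime_slope": 8,
      "mortality": {
        "form": "mortality_expquad",
        "params": {
          "b1": 10.271,
          "b2": -0.909,
          "b3": 0.019
        },
        "scale": "percent"
      }
    },
    "larva": {
      "dev_rate": {
        "form": "briere1",
        "params": {
          "a": 8.13e-05,
          "Tmin": 10,
          "Tmax": 38
        }
      },
      "devtime_slope": 8,
      "mortality": {
        "form": "mortality_expquad",
        "params": {
          "b1": 9.621,
          "b2": -0.453,
          "b3": 0.009
        },
        "scale": "percent"
      }
    },
    "pupa": {
      "dev_rate": {
        "form": "briere1",
        "params": {
          "a": 6.22e-05,
          "Tmin": 10,
          "Tmax": 38
        }
      },
      "devtime_slope": 8,
      "mortality": {
        "form": "mortality_expquad",
        "params": {
          "b1": 7.178,
          "b2": -0.57,
          "b3": 0.014
        },
        "scale": "percent"
      }
    }
  },
  "female_senescence": {
    "form": "senescence_exponential",
    "params": {
      "b1": 0.0098,
      "b2": 0.0403
    }
  },
  "male_senescence": {
    "form": "senescence_exponential",
    "params": {
      "b1": 0.0049,
      "b2": 0.0689
    }
  },
  "fecundity": {
    "form": "fecundity_exppoly",
    "params": {
      "b1": -7.851,
      "b2": 1.064,
      "b3": -0.019
    }
  },
  "oviposition": {
    "form": "ovip_logistic",
    "params": {
      "a": 3.94859,
      "b": -3.43037
    }
  },
  "female_ratio": 0.5,
  "adult_slope": "Inf"
}
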