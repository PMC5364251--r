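{
  "description": "Published OLS worked example: body mass index (BMI) regressed on parenthood (with children / childless) and age group (young / middle / older) in a pooled Dutch sample, n = 3314. Cell counts and the printed coefficients for dummy, effect, and weighted effect coding, each without (model1) and with (model2) interactions. Printed values are rounded to 2 decimals.",
  "factor_a": { "name": "children", "levels": ["with", "childless"], "omitted": "with" },
  "factor_b": { "name": "age", "levels": ["young", "middle", "older"], "omitted": "young" },
  "cell_counts": {
    "with": { "young": 99, "middle": 1624, "older": 531 },
    "childless": { "young": 511, "middle": 487, "older": 62 }
  },
  "dummy_model2": {
    "intercept": 24.88,
    "children": { "childless": -1.92 },
    "age": { "middle": 0.46, "older": 1.22 },
    "interaction": { "childless:middle": 1.22, "childless:older": 1.21 }
  },
  "printed": {
    "dummy": {
      "model1": {
        "intercept": 24.02,
        "children": { "childless": -0.90 },
        "age": { "middle": 1.36, "older": 2.09 }
      },
      "model2": {
        "intercept": 24.88,
        "children": { "childless": -1.92 },
        "age": { "middle": 0.46, "older": 1.22 },
        "interaction": { "childless:middle": 1.22, "childless:older": 1.21 }
      }
    },
    "effect": {
      "model1": {
        "intercept": 24.73,
        "children": { "with": 0.45, "childless": -0.45 },
        "age": { "young": -1.15, "middle": 0.21, "older": 0.94 }
      },
      "model2": {
        "intercept": 24.88,
        "children": { "with": 0.56, "childless": -0.56 },
        "age": { "young": -0.97, "middle": 0.11, "older": 0.86 },
        "interaction": {
          "with:young": 0.41, "with:middle": -0.21, "with:older": -0.20,
          "childless:young": -0.41, "childless:middle": 0.21, "childless:older": 0.20
        }
      }
    },
    "wec": {
      "model1": {
        "intercept": 24.98,
        "children": { "with": 0.29, "childless": -0.61 },
        "age": { "young": -1.24, "middle": 0.12, "older": 0.85 }
      },
      "model2": {
        "intercept": 24.98,
        "children": { "with": 0.29, "childless": -0.61 },
        "age": { "young": -1.24, "middle": 0.12, "older": 0.85 },
        "interaction": {
          "with:young": 0.86, "with:middle": -0.05, "with:older": -0.02,
          "childless:young": -0.17, "childless:middle": 0.15, "childless:older": 0.17
        }
      }
    }
  }
}
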