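{
  "name": "mpz-hplc-uv",
  "description": "Uncertainty budget for the HPLC-UV assay of Metopimazine (MPZ) content (%) in an injectable solution. Content model: (At/Ast) * (Pt/Vt1) * (Vp/Vt2) * (Vt/VSample) * P * delta_r * Cx * VmDose * 100, with VmDose = 0.1 mL/mg (the 1 mL / 10 mg dose ratio) carrying no uncertainty.",
  "model": {
    "numerator": ["At", "Pt", "Vp", "Vt"],
    "denominator": ["Ast", "Vt1", "Vt2", "VSample"],
    "factors": ["P", "delta_r", "Cx"],
    "constants": { "VmDose": 0.1, "scale": 100 }
  },
  "quantities": {
    "delta_r": {
      "description": "Method repeatability (pooled over 3 runs x 6 replicates), as a unit-valued relative-effect factor",
      "value": 1, "unit": "1", "relative_uncertainty": 0.0005, "dof": 17
    },
    "Cx": {
      "description": "Predicted concentration from the calibration curve (0.2005 mg/mL at the working level), as a unit-valued relative-effect factor; u = 0.0004 mg/mL at 0.2 mg/mL",
      "value": 1, "unit": "1", "relative_uncertainty": 0.002, "dof": 13
    },
    "At": {
      "description": "Peak area of Metopimazine in the test solution",
      "value": 70.509, "unit": "area", "standard_uncertainty": 0.0022, "dof": 5
    },
    "Ast": {
      "description": "Peak area of Metopimazine in the standard solution",
      "value": 70.714, "unit": "area", "standard_uncertainty": 0.0022, "dof": 5
    },
    "Pt": {
      "description": "Mass of reference substance weighed",
      "value": 100, "unit": "mg", "standard_uncertainty": 0.01155, "dof": "inf"
    },
    "Vt1": {
      "description": "Dilution volume of the standard stock solution (100 mL flask)",
      "value": 100, "unit": "mL", "standard_uncertainty": 0.06339, "dof": "inf"
    },
    "Vt2": {
      "description": "Dilution volume of the aliquot taken from the stock solution (25 mL flask)",
      "value": 25, "unit": "mL", "standard_uncertainty": 0.02034, "dof": "inf"
    },
    "Vp": {
      "description": "Volume taken from the standard stock solution (5 mL pipette)",
      "value": 5, "unit": "mL", "standard_uncertainty": 0.00659, "dof": "inf"
    },
    "Vt": {
      "description": "Volume of the test solution (100 mL flask)",
      "value": 100, "unit": "mL", "standard_uncertainty": 0.06339, "dof": "inf"
    },
    "VSample": {
      "description": "Volume of specimen (2 mL pipette)",
      "value": 2, "unit": "mL", "standard_uncertainty": 0.0042, "dof": "inf"
    },
    "P": {
      "description": "Purity of the Metopimazine reference standard (certificate 0.9999 +/- 0.0001, rectangular)",
      "value": 0.9999, "unit": "1", "standard_uncertainty": 0.000058, "dof": "inf"
    }
  },
  "distributions": {
    "delta_r": {
      "repeatability": { "family": "normal", "mean": 1, "sd": 0.0005 }
    },
    "Cx": {
      "calibration": { "family": "normal", "mean": 0.2, "sd": 0.0004 }
    },
    "At": {
      "instrument": { "family": "normal", "mean": 70.509, "sd": 0.0022 }
    },
    "Ast": {
      "instrument": { "family": "normal", "mean": 70.714, "sd": 0.0022 }
    },
    "VSample": {
      "calibration": { "family": "triangular", "a": 1.99, "b": 2.01 },
      "temperature": { "family": "rectangular", "a": 1.99832, "b": 2.00168 }
    },
    "Pt": {
      "linearity": { "family": "rectangular", "a": 99.98, "b": 100.02 }
    },
    "Vt1": {
      "calibration": { "family": "triangular", "a": 99.9, "b": 100.1 },
      "temperature": { "family": "rectangular", "a": 99.916, "b": 100.084 }
    },
    "Vt2": {
      "calibration": { "family": "triangular", "a": 24.96, "b": 25.04 },
      "temperature": { "family": "rectangular", "a": 24.979, "b": 25.021 }
    },
    "Vp": {
      "calibration": { "family": "triangular", "a": 4.985, "b": 5.015 },
      "temperature": { "family": "rectangular", "a": 4.9958, "b": 5.0042 }
    },
    "Vt": {
      "calibration": { "family": "triangular", "a": 99.9, "b": 100.1 },
      "temperature": { "family": "rectangular", "a": 99.916, "b": 100.084 }
    },
    "P": {
      "certificate": { "family": "rectangular", "a": 0.9998, "b": 1.0000,
        "note": "bounds from the certificate half-width +/- 0.0001 around 0.9999" }
    }
  },
  "reference": {
    "note": "Published values reported alongside the budget; kept as metadata, not recomputed. The published content 99.41 is not reproduced by the product model at nominal values (which gives 99.700); it equals (At/Ast)^2 * P * 100 to four significant figures.",
    "reported_content_pct": 99.41,
    "reported_u_pct": 0.3426,
    "reported_U_pct": 0.6852,
    "reported_k": 2,
    "reported_mcs": {
      "mean": 99.3822, "median": 99.3817, "sd": 0.3189,
      "expanded": 0.6228, "skewness": 0.0085, "k": 1.9529,
      "interval": [98.7623, 100.0079]
    },
    "reported_shares_pct": { "VSample": 39.9, "Cx": 36.2 },
    "u_hplc_uv": 0.0022
  }
}
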