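{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "golgisim run report",
  "type": "object",
  "required": ["scenario", "parameters", "convergence", "species"],
  "properties": {
    "scenario": { "type": "string" },
    "parameters": {
      "type": "object",
      "required": ["n_cisternae", "period", "omega", "n_sites", "T_ER",
                   "topology", "boundary", "er_access", "site_sharing",
                   "er_cargo_only", "dt", "tol", "max_periods"],
      "properties": {
        "n_cisternae": { "type": "integer" },
        "period": { "type": "number" },
        "omega": { "type": "number" },
        "n_sites": { "type": "number" },
        "T_ER": { "type": "number" },
        "topology": { "type": "string", "enum": ["local", "unrestricted"] },
        "boundary": { "type": "string", "enum": ["open", "closed"] },
        "er_access": {
          "type": "string",
          "enum": ["none", "first_cisterna_only", "all_cisternae"]
        },
        "site_sharing": { "type": "string", "enum": ["all", "by_class"] },
        "er_cargo_only": { "type": "boolean" },
        "dt": { "type": "number" },
        "tol": { "type": "number" },
        "max_periods": { "type": "integer" }
      }
    },
    "convergence": {
      "type": "object",
      "required": ["converged", "n_periods_used", "residual"],
      "properties": {
        "converged": { "type": "boolean" },
        "n_periods_used": { "type": "integer" },
        "residual": { "type": "number" },
        "clamp_count": { "type": "integer" }
      }
    },
    "species": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["species", "argmax", "peak_value", "er_fraction",
                     "monotonicity"],
        "properties": {
          "species": { "type": "string" },
          "argmax": { "type": "integer" },
          "peak_value": { "type": "number" },
          "er_fraction": { "type": "number" },
          "monotonicity": {
            "type": "string",
            "enum": ["constant", "increasing", "decreasing", "unimodal",
                     "irregular"]
          }
        }
      }
    },
    "fitted_exponent": { "type": "object" },
    "profiles_file": { "type": "string" }
  }
}
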