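{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "depfield run configuration",
  "description": "Schema of the YAML run configuration. Lengths are strings with unit suffix (m, mm, um, nm) or bare numbers in metres.",
  "type": "object",
  "required": ["geometry"],
  "properties": {
    "geometry": {
      "type": "object",
      "required": ["width", "height"],
      "properties": {
        "width": {"description": "channel width L (y extent)"},
        "height": {"description": "channel height h (z extent)"},
        "n_bottom": {"type": "integer", "minimum": 2},
        "n_top": {"type": "integer", "minimum": 2},
        "n_electrodes": {"type": "integer", "minimum": 2,
                         "description": "shorthand when both walls match"}
      }
    },
    "medium": {
      "type": "object",
      "properties": {
        "rel_permittivity": {"type": "number", "exclusiveMinimum": 0},
        "conductivity": {"type": "number", "minimum": 0, "description": "S/m"},
        "wall_rel_permittivity": {"type": "number", "exclusiveMinimum": 0}
      }
    },
    "particle": {
      "type": "object",
      "properties": {
        "radius": {"description": "length with unit"},
        "rel_permittivity": {"type": "number", "exclusiveMinimum": 0},
        "conductivity": {"type": "number", "minimum": 0, "description": "S/m"}
      }
    },
    "drive": {
      "type": "object",
      "properties": {
        "angular_frequency": {"type": "number", "exclusiveMinimum": 0,
                              "description": "rad/s"},
        "cm_real": {"type": "number", "minimum": -0.5, "maximum": 1,
                    "description": "Re(beta) override"}
      }
    },
    "voltages": {
      "type": "object",
      "required": ["bottom"],
      "properties": {
        "bottom": {"type": "array", "items": {"type": "number"},
                   "description": "volts, one per bottom electrode, increasing y"},
        "top": {"type": "array", "items": {"type": "number"}}
      }
    },
    "model": {
      "type": "object",
      "properties": {"truncation_P": {"type": "integer", "minimum": 1}}
    },
    "solver": {
      "type": "object",
      "properties": {"spacing": {"description": "grid target spacing, length"}}
    },
    "roi": {
      "type": "object",
      "properties": {
        "y_range": {"type": "array", "minItems": 2, "maxItems": 2},
        "z_range": {"type": "array", "minItems": 2, "maxItems": 2}
      }
    },
    "seed": {"type": "integer"}
  }
}
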