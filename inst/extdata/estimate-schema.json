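{
  "title": "cortiprof thickness estimate record",
  "required": ["method", "thickness", "half_thickness", "regularized", "config_hash"],
  "types": {
    "method": "string",
    "thickness": "number",
    "half_thickness": "number",
    "K_used": "number",
    "bmc_cort": "number",
    "regularized": "boolean",
    "config_hash": "string"
  }
}
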