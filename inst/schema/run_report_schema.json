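{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "segspeech pipeline run report",
  "type": "object",
  "required": ["software", "seed", "config_hash", "counts", "battery",
               "probe", "mediation", "serial"],
  "properties": {
    "software": {
      "type": "object",
      "required": ["package", "version"],
      "properties": {
        "package": {"type": "string"},
        "version": {"type": "string"}
      }
    },
    "seed": {"type": "integer"},
    "config_hash": {"type": "string"},
    "counts": {
      "type": "object",
      "required": ["n_in", "n_screened_out", "n_analysis"],
      "properties": {
        "n_in": {"type": "integer"},
        "n_screened_out": {"type": "integer"},
        "n_analysis": {"type": "integer"},
        "cooks_flagged_per_model": {"type": "object"}
      }
    },
    "exclusions": {"type": "object"},
    "battery": {"type": "object"},
    "significant": {"type": "object"},
    "probe": {
      "type": "object",
      "required": ["network", "outcome", "simple_slopes", "johnson_neyman"]
    },
    "mediation": {
      "type": "object",
      "required": ["mediator", "outcome", "paths", "acme", "ade", "total"]
    },
    "serial": {
      "type": "object",
      "required": ["prerequisite", "licensed"]
    },
    "transcripts": {"type": "object"}
  }
}
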