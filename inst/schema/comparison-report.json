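{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "mmcompare comparison report",
  "type": "object",
  "required": ["tool", "version", "operation", "estimates", "statistics",
               "verdicts", "warnings"],
  "properties": {
    "tool": {"type": "string", "const": "mmcompare"},
    "version": {"type": "string"},
    "operation": {"type": "string"},
    "inputs": {"type": "object"},
    "estimates": {"type": "object"},
    "intervals": {
      "type": ["object", "null"],
      "additionalProperties": {
        "type": "object",
        "required": ["estimate", "lower", "upper", "level"],
        "properties": {
          "estimate": {"type": "number"},
          "lower": {"type": "number"},
          "upper": {"type": "number"},
          "level": {"type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 1}
        }
      }
    },
    "statistics": {"type": "object"},
    "verdicts": {"type": "object"},
    "warnings": {"type": "array", "items": {"type": "string"}},
    "seed": {"type": ["integer", "null"]}
  }
}
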