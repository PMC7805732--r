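{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "kneemoments run report",
  "type": "object",
  "required": ["image_id", "config_fingerprint", "status", "stages"],
  "properties": {
    "image_id": { "type": "string" },
    "config_fingerprint": { "type": "string", "pattern": "^[0-9a-f]{8}$" },
    "status": { "enum": ["ok", "failed"] },
    "failed_stage": { "type": "string" },
    "error": { "type": "string" },
    "contour_count": { "type": "integer", "minimum": 0 },
    "stages": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["seconds", "ok"],
        "properties": {
          "seconds": { "type": "number", "minimum": 0 },
          "ok": { "type": "boolean" }
        }
      }
    },
    "roi": {
      "type": "object",
      "required": ["row_start", "row_end", "col_start", "col_end"],
      "properties": {
        "row_start": { "type": "integer", "minimum": 0 },
        "row_end": { "type": "integer", "minimum": 1 },
        "col_start": { "type": "integer", "minimum": 0 },
        "col_end": { "type": "integer", "minimum": 1 }
      }
    },
    "mask_summary": {
      "type": "object",
      "required": ["foreground_pixels"],
      "properties": {
        "foreground_pixels": { "type": "integer", "minimum": 0 },
        "dice": { "type": "number", "minimum": 0, "maximum": 1 }
      }
    },
    "features": {
      "type": "object",
      "required": ["phi1", "phi2", "phi3", "phi4", "phi5", "phi6", "phi7"],
      "additionalProperties": { "type": "number" }
    },
    "predicted": {
      "enum": ["Normal", "Doubtful", "Mild", "Moderate", "Severe"]
    }
  }
}
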