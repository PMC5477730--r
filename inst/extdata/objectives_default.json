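{
  "d95": {"kind": "target", "target": 100, "per_protocol_tol": 0.05, "acceptable_tol": 2},
  "d5": {"kind": "upper", "per_protocol": 107, "acceptable": 110},
  "d98": {"kind": "lower", "per_protocol": 95, "acceptable": 90},
  "hotspot_outside": {"kind": "upper", "per_protocol": 107, "acceptable": 110}
}
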