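{
  "schema_version": "1.0",
  "out_dir": "cbctdose-demo",
  "seed": 1,
  "protocols": "factory",
  "dose_table": "bundled",
  "fractions": 39
}
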