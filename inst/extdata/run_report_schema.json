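{
  "required": ["package_version", "config", "stages", "outputs", "seed"]
}
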