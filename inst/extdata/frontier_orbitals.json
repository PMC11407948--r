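{
  "FA": {"e_homo": -0.234, "e_lumo": -0.177},
  "CA": {"e_homo": -0.295, "e_lumo": -0.174}
}
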