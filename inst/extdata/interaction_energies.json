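{
  "FA": {"e_electrostatic": -242.5, "e_vdw": 27.5},
  "CA": {"e_electrostatic": 27.81, "e_vdw": -197.8},
  "mix_1_1": {"e_electrostatic": -257.9, "e_vdw": 26.8}
}
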