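molecule,angle,range_min,range_max
FA,C3-O1-C10,105,127
FA,O3-C9-O4,117,133
FA,O4-C9-C8,108,128
CA,O4-C9-C8,114,124
CA,O3-C9-C8,113,125
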