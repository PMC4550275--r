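# 17 conserved elongase residues, positions on the Elovl5 reference protein.
125K, 128E, 131DT, 137L, 151HH, 178N, 182H, 185MY, 188YY, 208T, 250LF, 254F
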