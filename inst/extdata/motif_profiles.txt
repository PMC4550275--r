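# Degenerate motif profile for Fad / Elovl structural screening.
# grammar per position: literal residue | X (any) | A/B (either residue)
haeme = HPGG
fad_box1 = HXXXH
fad_box2 = HXXHH
fad_box3 = QXXHH
elovl_box = HXXHH
fad_box1_consensus = HDF/YGH
fad_box2_consensus = HY/FQ/LHH
fad_box3_consensus = QI/VEHH
elovl_box_consensus = HVF/YHH
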