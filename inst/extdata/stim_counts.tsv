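label	k1	n1	k2	n2
all_sites	9	31	0	21
face_selective	6	17	0	7
non_selective	3	14	0	14
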