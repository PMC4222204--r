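population	group
L1	lignotuberous
L2	lignotuberous
L3	lignotuberous
L4	lignotuberous
L5	lignotuberous
L6	lignotuberous
E1	epicormic
E2	epicormic
E3	epicormic
E4	epicormic
E5	epicormic
E6	epicormic
E7	epicormic
E8	epicormic
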