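# Placeholder (synthetic) partial charges for the default
# 9-residue glycan mimic of make_glycan_mimic(2, 3, 2, fucose = TRUE):
# neutral C/O/H groups with one extra proton charge on the PA-tag
# hydrogen and one on the distal alpha1-3-arm hydrogen (net +2).
# atom_index charge_e
0 0.15
1 -0.40
2 1.25
3 0.15
4 -0.40
5 0.25
6 0.15
7 -0.40
8 0.25
9 0.15
10 -0.40
11 0.25
12 0.15
13 -0.40
14 0.25
15 0.15
16 -0.40
17 1.25
18 0.15
19 -0.40
20 0.25
21 0.15
22 -0.40
23 0.25
24 0.15
25 -0.40
26 0.25
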