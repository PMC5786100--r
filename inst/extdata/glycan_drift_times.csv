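species,mz,drift_ms,reported_ccs_A2
G0F-GN(3),669.8,5.31,371
G0F-GN(6),669.8,5.73,388
G0,698.3,6.07,402
G0F,771.3,6.76,431
G1(3),779.3,5.80,391
G1(6),779.3,6.69,428
G1F(3),852.3,6.62,425
G1F(6),852.3,6.97,440
G2,860.3,6.42,417
G2F,933.4,7.04,442
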