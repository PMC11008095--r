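PCMRESP-MOL 1
units angstrom
total_charge 0
counts 3 2
ATOMS
O  0.000000000000e+00  0.000000000000e+00  0.000000000000e+00 -8.340000000000e-01  4.650000000000e-01  7.000000000000e-01
H  9.572000000000e-01  0.000000000000e+00  0.000000000000e+00  4.170000000000e-01  1.350000000000e-01  4.000000000000e-01
H -2.399872084090e-01  9.266272064860e-01  0.000000000000e+00  4.170000000000e-01  1.350000000000e-01  4.000000000000e-01
BONDS
1 2
1 3
EQUIV
2 3
END
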