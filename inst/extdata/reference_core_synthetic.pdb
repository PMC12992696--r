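MODEL        1
HETATM    1  N1  LIG A 900       3.950   1.500   4.200  1.00  0.00           N
HETATM    2  C2  LIG A 900       3.200   1.500   3.300  1.00  0.00           C
HETATM    3  C3  LIG A 900       3.100   1.500   5.200  1.00  0.00           C
HETATM    4  C3A LIG A 900       1.900   1.500   4.500  1.00  0.00           C
HETATM    5  C4  LIG A 900       1.200   1.500   5.710  1.00  0.00           C
HETATM    6  C5  LIG A 900      -0.200   1.500   5.710  1.00  0.00           C
HETATM    7  C6  LIG A 900      -0.900   1.500   4.500  1.00  0.00           C
HETATM    8  C7  LIG A 900      -0.200   1.500   3.290  1.00  0.00           C
HETATM    9  C7A LIG A 900       1.200   1.500   3.290  1.00  0.00           C
ENDMDL
END
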