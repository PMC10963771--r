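benzene (synthetic coordinates)
  nfindex

 12 12  0  0  0  0  0  0  0  0999 V2000
    1.2124    0.7000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    1.4000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.2124    0.7000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.2124   -0.7000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000   -1.4000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.2124   -0.7000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.1651    1.2500    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    2.5000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.1651    1.2500    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.1651   -1.2500    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000   -2.5000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.1651   -1.2500    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  2  3  1  0  0  0  0
  3  4  1  0  0  0  0
  4  5  1  0  0  0  0
  5  6  1  0  0  0  0
  6  1  1  0  0  0  0
  1  7  1  0  0  0  0
  2  8  1  0  0  0  0
  3  9  1  0  0  0  0
  4 10  1  0  0  0  0
  5 11  1  0  0  0  0
  6 12  1  0  0  0  0
M  END
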