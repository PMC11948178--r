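synthetic PBD-style linker-payload (sg3584-like, synthetic)
  adcbiotx

 27 29  0  0  0  0  0  0  0  0999 V2000
    0.1000    0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
    0.2000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.3000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.4000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.5000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.6000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.7000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.8000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.9000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.1000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.2000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
    1.3000    0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
    1.4000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.5000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.6000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.7000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.8000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.9000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.1000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.2000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.3000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.4000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.5000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.6000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.7000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  2  3  1  0  0  0  0
  3  4  2  0  0  0  0
  4  5  1  0  0  0  0
  5  1  1  0  0  0  0
  2  6  2  0  0  0  0
  5  7  2  0  0  0  0
  1  8  1  0  0  0  0
  8  9  1  0  0  0  0
  9 10  1  0  0  0  0
 10 11  1  0  0  0  0
 11 12  2  0  0  0  0
 11 13  1  0  0  0  0
 13 14  1  0  0  0  0
 13 15  1  0  0  0  0
 15 16  1  0  0  0  0
 16 17  1  0  0  0  0
 17 19  1  0  0  0  0
 18 19  1  0  0  0  0
 19 20  2  0  0  0  0
 20 21  1  0  0  0  0
 21 22  2  0  0  0  0
 22 23  1  0  0  0  0
 23 18  2  0  0  0  0
 23 24  1  0  0  0  0
 24 25  2  0  0  0  0
 25 26  1  0  0  0  0
 26 27  2  0  0  0  0
 27 18  1  0  0  0  0
M  END
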