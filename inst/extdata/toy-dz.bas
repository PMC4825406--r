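# Split-valence toy basis: STO-3G-type core plus an uncontracted outer
# function per valence shell. Gives H two s functions and first-row atoms a
# doubled valence space, enough for non-trivial orbital optimization at
# desk scale.
element H
S
  1.30975638   1.0
S
  0.23313597   1.0
element C
S
  71.6168370   0.15432897
  13.0450960   0.53532814
  3.5305122    0.44463454
SP
  2.9412494   -0.09996723   0.15591627
  0.6834831    0.39951283   0.60768372
SP
  0.2222899    1.0          1.0
element N
S
  99.1061690   0.15432897
  18.0523120   0.53532814
  4.8856602    0.44463454
SP
  3.7804559   -0.09996723   0.15591627
  0.8784966    0.39951283   0.60768372
SP
  0.2857144    1.0          1.0
element O
S
  130.7093200  0.15432897
  23.8088610   0.53532814
  6.4436083    0.44463454
SP
  5.0331513   -0.09996723   0.15591627
  1.1695961    0.39951283   0.60768372
SP
  0.3803890    1.0          1.0
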