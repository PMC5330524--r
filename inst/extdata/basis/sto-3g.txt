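# STO-3G minimal basis, standard published exponents/coefficients
# (coefficients refer to normalized primitives)
ATOM H
S 3
   3.425250914    0.1543289673
   0.6239137298   0.5353281423
   0.1688554040   0.4446345422
ATOM He
S 3
   6.362421394    0.1543289673
   1.158922999    0.5353281423
   0.3136497915   0.4446345422
ATOM C
S 3
  71.6168370     0.1543289673
  13.0450960     0.5353281423
   3.5305122     0.4446345422
SP 3
   2.9412494    -0.09996723   0.15591627
   0.6834831     0.39951283   0.60768372
   0.2222899     0.70011547   0.39195739
ATOM N
S 3
  99.1061690     0.1543289673
  18.0523120     0.5353281423
   4.8856602     0.4446345422
SP 3
   3.7804559    -0.09996723   0.15591627
   0.8784966     0.39951283   0.60768372
   0.2857144     0.70011547   0.39195739
ATOM O
S 3
 130.7093200     0.1543289673
  23.8088610     0.5353281423
   6.4436083     0.4446345422
SP 3
   5.0331513    -0.09996723   0.15591627
   1.1695961     0.39951283   0.60768372
   0.3803890     0.70011547   0.39195739
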