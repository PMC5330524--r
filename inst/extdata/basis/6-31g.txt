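# 6-31G split-valence basis, standard published exponents/coefficients
ATOM H
S 3
  18.7311370     0.03349460
   2.8253937     0.23472695
   0.6401217     0.81375733
S 1
   0.1612778     1.0
ATOM C
S 6
3047.5248800    0.0018347
 457.3695180    0.0140373
 103.9486850    0.0688426
  29.2101553    0.2321844
   9.2866630    0.4679413
   3.1639270    0.3623120
SP 3
   7.8682724   -0.1193324   0.0689991
   1.8812885   -0.1608542   0.3164240
   0.5442493    1.1434564   0.7443083
SP 1
   0.1687144    1.0         1.0
ATOM N
S 6
4173.5114600    0.0018348
 627.4579110    0.0139950
 142.9020930    0.0685870
  40.2343293    0.2322410
  12.8202129    0.4690700
   4.3904370    0.3604550
SP 3
  11.6263619   -0.1149612   0.0675797
   2.7162798   -0.1691175   0.3239073
   0.7722184    1.1458520   0.7408951
SP 1
   0.2120315    1.0         1.0
ATOM O
S 6
5484.6716600    0.0018311
 825.2349460    0.0139501
 188.0469580    0.0684451
  52.9645000    0.2327143
  16.8975704    0.4701930
   5.7996353    0.3585209
SP 3
  15.5396162   -0.1107775   0.0708743
   3.5999336   -0.1480263   0.3397528
   1.0137618    1.1307670   0.7271586
SP 1
   0.2700058    1.0         1.0
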