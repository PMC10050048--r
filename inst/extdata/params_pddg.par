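# PDDG/MNDO parameter values (optimization starting point; the PDDG Gaussian
# core-repulsion corrections themselves are not part of this engine).
H alpha   2.491813
H beta_s  -7.493504
H u_ss    -11.724114
H zeta_s  1.322431
H e_isol  -12.015956
C alpha   2.555522
C beta_s  -18.841334
C beta_p  -7.922234
C u_ss    -53.837582
C u_pp    -39.936409
C zeta_s  1.809817
C zeta_p  1.825008
C e_isol  -123.864410
N alpha   2.843678
N beta_s  -20.375774
N beta_p  -21.085373
N u_ss    -71.871894
N u_pp    -58.216617
N zeta_s  2.231424
N zeta_p  2.253460
N e_isol  -206.466630
O alpha   3.238842
O beta_s  -33.606336
O beta_p  -27.984442
O u_ss    -97.884970
O u_pp    -77.342674
O zeta_s  2.569172
O zeta_p  2.697152
O e_isol  -310.879750
F alpha   3.322382
F beta_s  -67.827612
F beta_p  -40.924818
F u_ss    -134.220380
F u_pp    -107.155960
F zeta_s  4.328519
F zeta_p  2.905042
F e_isol  -488.703240
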