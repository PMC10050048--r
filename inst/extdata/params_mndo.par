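# Original MNDO parameters for H, C, N, O, F.
# alpha in 1/Angstrom, beta/U/E_isol in eV, zeta in 1/bohr.
H alpha   2.544134
H beta_s  -6.989064
H u_ss    -11.906276
H zeta_s  1.331967
H e_isol  -11.906276
C alpha   2.546380
C beta_s  -18.985044
C beta_p  -7.934122
C u_ss    -52.279745
C u_pp    -39.205558
C zeta_s  1.787537
C zeta_p  1.787537
C e_isol  -120.500606
N alpha   2.861342
N beta_s  -20.495758
N beta_p  -20.495758
N u_ss    -71.932122
N u_pp    -57.172319
N zeta_s  2.255614
N zeta_p  2.255614
N e_isol  -202.566201
O alpha   3.160604
O beta_s  -32.688082
O beta_p  -32.688082
O u_ss    -99.643090
O u_pp    -77.797472
O zeta_s  2.699905
O zeta_p  2.699905
O e_isol  -317.868506
F alpha   3.4196606
F beta_s  -48.290466
F beta_p  -36.508540
F u_ss    -131.071550
F u_pp    -105.782140
F zeta_s  2.848487
F zeta_p  2.848487
F e_isol  -476.683780
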