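# Reparameterized MNDO values for H, C, N, O, F (end point of the limited
# trust-region optimization; unphysical magnitudes for some fluorine and
# oxygen parameters are a documented feature of that minimum).
H alpha   2.993408
H beta_s  -7.334656
H u_ss    -10.314472
H zeta_s  1.124161
H e_isol  -11.423363
C alpha   2.660499
C beta_s  -13.719865
C beta_p  -6.970837
C u_ss    -47.292652
C u_pp    -40.221274
C zeta_s  2.326858
C zeta_p  1.637021
C e_isol  -112.533538
N alpha   3.021163
N beta_s  -17.522551
N beta_p  -15.550446
N u_ss    -64.905273
N u_pp    -57.638287
N zeta_s  2.914488
N zeta_p  2.126141
N e_isol  -189.262258
O alpha   3.334554
O beta_s  -73.616234
O beta_p  -22.327739
O u_ss    -94.106196
O u_pp    -78.565181
O zeta_s  5.5944705
O zeta_p  2.425014
O e_isol  -309.024988
F alpha   3.590480
F beta_s  -1753.340685
F beta_p  -22.382738
F u_ss    -107.380890
F u_pp    -106.952003
F zeta_s  50.167806
F zeta_p  2.463961
F e_isol  -434.411284
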