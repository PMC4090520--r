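# Simulated eight-treatment repeated-measures study (synthetic).
# Generated from the equicorrelated one-way model with all true means 1,
# sigma = 1.0..4.5 by 0.5, rho = 0.2, sigma_alpha = 1.
# T: 4
group,n,mu_hat,ss
A,5,1.806,12.835
B,5,2.053,40.928
C,5,0.179,10.731
D,5,1.492,32.809
E,10,0.369,111.134
F,10,1.995,430.336
G,10,-1.163,290.230
H,10,0.743,653.191
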