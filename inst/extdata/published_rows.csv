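system,cutoff,sensitivity,specificity,ppv,npv,plr,nlr,accuracy,n_pos,n_neg
alvarado,7,88.4,63.6,96.4,33.3,2.43,0.18,86.3,121,11
air,5,77.7,81.8,97.9,25,4.27,0.27,78.03,121,11
ripasa,7.5,96.7,72.7,97.5,66.7,3.54,0.05,94.6,121,11
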