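trait,delta,lrt
mean,1.55,0.625
lower,2.99,5.16
upper,2.86,3.10
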