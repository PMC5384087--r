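model,k,logL
BVAR,2,-122.93
BVAR-DCST,3,-122.93
BCST,1,-125.39
BVAR-DVAR,4,-122.93
BCST-DCST,2,-125.39
BCST-DVAR,3,-125.39
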