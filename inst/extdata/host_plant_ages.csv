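label,median,ci_low,ci_high,used_as_calibration
Stem of Solanaceae,64.0,48,83,TRUE
Crown of Solanaceae,42.2,26.8,55.2,FALSE
Crown of x=12 clade,39.5,21.9,44.4,FALSE
Crown of Solanum,20.9,14.5,29.5,FALSE
Stem of Capsicum,19.0,11.5,25,TRUE
Stem of Schultesianthus,17.0,7,24,TRUE
Stem of Brugmansia,10.5,5,14,TRUE
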