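source,months_after_planting,training_system,minimum,maximum,range,average,standard_deviation
field,15,hedgerow,0.59,2.26,1.67,1.67,0.37
field,15,intensive,0.70,2.30,1.60,1.56,0.28
field,27,hedgerow,1.15,3.25,2.10,2.51,0.30
field,27,intensive,1.25,2.95,1.70,2.34,0.31
obia,15,hedgerow,0.00,2.78,2.78,1.33,0.55
obia,15,intensive,0.34,2.28,1.95,1.30,0.39
obia,27,hedgerow,0.89,3.04,2.15,2.29,0.32
obia,27,intensive,1.25,3.09,1.84,2.22,0.34
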