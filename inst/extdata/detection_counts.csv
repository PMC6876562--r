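months_after_planting,training_system,field_trees,detected_trees
15,hedgerow,806,764
15,intensive,244,228
27,hedgerow,804,794
27,intensive,243,243
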