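population	n	n_HH	n_HC	n_CC
Taiwanese	1244	653	490	101
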