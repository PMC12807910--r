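color,difficulty,n_false,n_correct
blue,easy,587,1386
blue,hard,625,1348
red,easy,636,1346
red,hard,838,1112
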