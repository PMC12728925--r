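name: example-2tgt
oracle: levenshtein
targets:
- NONNOOC1CCCCC1
- CCNOCCOC(NN)O
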