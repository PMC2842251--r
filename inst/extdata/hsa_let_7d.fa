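>hsa-let-7d mature sequence
AGAGGUAGUAGGUUGCAUAGUU
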