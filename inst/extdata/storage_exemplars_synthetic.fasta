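>storage_exemplar_synthetic_1 synthetic glutamine-rich 2S-albumin-like exclusion exemplar (not a real deposited sequence)
QQENQGQSQEQQMEQQRQQQENQGQSQEQQMEQQRQQQENQGQSQEQQMEQQRQQQENQG
QSQEQQMEQQRQQQENQGQSQEQQMEQQRQQQENQGQSQEQQMEQQRQQQENQGQSQEQQ
MEQQRQQQENQGQSQEQQMEQQRQQQENQGQSQEQQMEQQRQQQENQGQSQEQQMEQQRQ
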