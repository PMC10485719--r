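task,overdiagnosis,underdiagnosis,mel_total
1,171,21,64
2,81,14,64
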