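S1	EUR
S2	EUR
S3	EAS
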