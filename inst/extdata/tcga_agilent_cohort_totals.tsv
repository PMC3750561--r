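quantity	value
downloaded_samples	2365
unique_samples	2210
removed_samples	155
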