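role	n_sites
foreground	1869
functional_segment	985
background	42535
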