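# Solve the default grid once; several test files reuse it.
default_grid <- solve_grid()
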