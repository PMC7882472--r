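class,species,specimens
generalist,38,2524
specialist,29,4182
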