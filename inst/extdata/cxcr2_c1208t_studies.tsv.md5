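85b1f964d309d57b295b21fd4ee74c5e
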