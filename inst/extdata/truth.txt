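G00008	gain
G00024	deletion
G00040	gain
G00056	deletion
G00072	gain
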