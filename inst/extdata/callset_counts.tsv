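callset	n_total	n_mosaic
final	4095	221
pre_filter	4909	1036
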