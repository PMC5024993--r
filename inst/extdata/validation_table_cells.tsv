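stage	predicted_label	assay	chosen	success	present	confirmed	informative
pre_filter	mosaic	sanger	47	37	20	14	37
pre_filter	germline_denovo	sanger	50	39	39	36	39
post_filter	mosaic	sanger	26	19	19	13	19
post_filter	germline_denovo	sanger	50	39	39	36	39
pre_filter	mosaic	phasing	342	51	51	29	51
pre_filter	germline_denovo	phasing	3742	443	443	416	443
post_filter	mosaic	phasing	221	30	30	26	30
post_filter	germline_denovo	phasing	3874	468	468	437	468
final	mosaic	pyro	11	11	11	9	11
final	germline_denovo	pyro	10	10	10	9	10
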