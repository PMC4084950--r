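snp_id	frequency	escaped_protospacer	fixed
snp_i	1	11	TRUE
snp_ii	0.62	13	FALSE
snp_iii	0.18	14	FALSE
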