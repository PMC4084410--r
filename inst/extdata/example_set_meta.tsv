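id	label	category	p_value	weight	active_rank
glioma	Glioma	pathway	1	1	1
ltp	Long-term potentiation	pathway	1	1	2
gnrh	GnRH signaling pathway	pathway	1	1	3
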