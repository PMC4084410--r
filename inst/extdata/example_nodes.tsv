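id	label	score	url
Calm1	Calm1	-0.9	
Calm2	Calm2	-0.5	
Calm3	Calm3	-0.7	
Kras	Kras	1.2	
Nr3c2	Nr3c2	0.4	
Plcb4	Plcb4	-1.1	
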