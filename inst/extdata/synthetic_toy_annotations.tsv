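sequence_id	sequence	kind	category	start	end
Q8BUZ1_like	MKSSLSAGTRLQDW	motif	Motif1	3	7
Q8BUZ1_like	MKSSLSAGTRLQDW	motif	Motif3	9	9
Q8BUZ1_like	MKSSLSAGTRLQDW	domain	Domain2	2	8
Q8BUZ1_like	MKSSLSAGTRLQDW	region	Region1	10	12
P_short	MAVLK	motif	Motif2	2	4
P_noent	GGSSAA
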