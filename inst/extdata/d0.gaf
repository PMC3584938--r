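!gaf-version: 2.1
GP	p1	p1		GO:0000004	GO_REF:0000000	EXP		P			protein	taxon:0000	20110101	gopred
GP	p2	p2		GO:0000004	GO_REF:0000000	EXP		P			protein	taxon:0000	20110101	gopred
GP	p2	p2		GO:0000003	GO_REF:0000000	EXP		P			protein	taxon:0000	20110101	gopred
GP	p3	p3		GO:0000005	GO_REF:0000000	EXP		P			protein	taxon:0000	20110101	gopred
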