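!gaf-version: 2.1
! Synthetic annotation rows for the worked CAFA targets: every hit subject
! carries only IEA evidence, so the non-IEA BLAST baseline has nothing to
! transfer.
GP	O26024	O26024		GO:0006457	GO_REF:0000000	IEA		P			protein	taxon:0000	20110101	gopred
GP	SYNQ0001	SYNQ0001		GO:0019860	GO_REF:0000000	IEA		P			protein	taxon:0000	20110101	gopred
GP	SYNQ0002	SYNQ0002		GO:0008152	GO_REF:0000000	IEA		P			protein	taxon:0000	20110101	gopred
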