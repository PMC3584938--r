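T06450	O26024	32.5	180	110	4	5	180	3	175	2e-12	88.2
T06299	SYNQ0001	41.0	150	85	2	1	148	2	150	5e-20	120.5
T06299	SYNQ0002	28.4	120	80	3	4	118	6	121	3e-04	45.0
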