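T06450	GO:0008152
T06450	GO:0044238
T06450	GO:0044237
T06450	GO:0043170
T06450	GO:0044260
T06450	GO:0019538
T06450	GO:0044267
T06450	GO:0006457
T06450	GO:0042026
T06299	GO:0019740
T06299	GO:0008152
T06299	GO:0034641
T06299	GO:0006139
T06299	GO:0006206
T06299	GO:0019860
T06299	GO:0006208
T06299	GO:0006212
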