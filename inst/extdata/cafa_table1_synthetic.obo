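format-version: 1.2
! Synthetic is_a scaffold holding the GO terms of two worked CAFA targets
! (T06450, T06299). The parentage below is a plausible reconstruction for
! desk-scale evaluation, not a Gene Ontology release.

[Term]
id: GO:0008150
name: biological_process
namespace: biological_process

[Term]
id: GO:0008152
name: metabolic process
namespace: biological_process
is_a: GO:0008150

[Term]
id: GO:0044238
name: primary metabolic process
namespace: biological_process
is_a: GO:0008152

[Term]
id: GO:0044237
name: cellular metabolic process
namespace: biological_process
is_a: GO:0008152

[Term]
id: GO:0043170
name: macromolecule metabolic process
namespace: biological_process
is_a: GO:0044238

[Term]
id: GO:0044260
name: cellular macromolecule metabolic process
namespace: biological_process
is_a: GO:0043170
is_a: GO:0044237

[Term]
id: GO:0019538
name: protein metabolic process
namespace: biological_process
is_a: GO:0043170

[Term]
id: GO:0044267
name: cellular protein metabolic process
namespace: biological_process
is_a: GO:0019538
is_a: GO:0044260

[Term]
id: GO:0006457
name: protein folding
namespace: biological_process
is_a: GO:0044267

[Term]
id: GO:0042026
name: protein refolding
namespace: biological_process
is_a: GO:0006457

[Term]
id: GO:0019740
name: nitrogen utilization
namespace: biological_process
is_a: GO:0008150

[Term]
id: GO:0034641
name: cellular nitrogen compound metabolic process
namespace: biological_process
is_a: GO:0044237

[Term]
id: GO:0006139
name: nucleobase, nucleoside, nucleotide and nucleic acid metabolic process
namespace: biological_process
is_a: GO:0034641
is_a: GO:0044238

[Term]
id: GO:0006206
name: pyrimidine base metabolic process
namespace: biological_process
is_a: GO:0006139

[Term]
id: GO:0019860
name: uracil metabolic process
namespace: biological_process
is_a: GO:0006206

[Term]
id: GO:0006208
name: pyrimidine base catabolic process
namespace: biological_process
is_a: GO:0006206

[Term]
id: GO:0006212
name: uracil catabolic process
namespace: biological_process
is_a: GO:0019860
is_a: GO:0006208
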