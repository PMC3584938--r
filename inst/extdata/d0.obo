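format-version: 1.2

[Term]
id: GO:0000001
name: R
namespace: biological_process

[Term]
id: GO:0000002
name: A
namespace: biological_process
is_a: GO:0000001 ! R

[Term]
id: GO:0000003
name: B
namespace: biological_process
is_a: GO:0000001 ! R

[Term]
id: GO:0000004
name: A1
namespace: biological_process
is_a: GO:0000002 ! A

[Term]
id: GO:0000005
name: A2
namespace: biological_process
is_a: GO:0000002 ! A
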