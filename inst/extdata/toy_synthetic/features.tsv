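gene01
gene02
gene03
gene04
gene05
gene06
gene07
gene08
gene09
gene10
gene11
gene12
gene13
gene14
gene15
gene16
gene17
gene18
gene19
gene20
gene21
gene22
gene23
gene24
gene25
gene26
gene27
gene28
gene29
gene30
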