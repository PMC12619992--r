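gene_id	is_de
gene01	TRUE
gene02	TRUE
gene03	TRUE
gene04	TRUE
gene05	TRUE
gene06	TRUE
gene07	FALSE
gene08	FALSE
gene09	FALSE
gene10	FALSE
gene11	FALSE
gene12	FALSE
gene13	FALSE
gene14	FALSE
gene15	FALSE
gene16	FALSE
gene17	FALSE
gene18	FALSE
gene19	FALSE
gene20	FALSE
gene21	FALSE
gene22	FALSE
gene23	FALSE
gene24	FALSE
gene25	FALSE
gene26	FALSE
gene27	FALSE
gene28	FALSE
gene29	FALSE
gene30	FALSE
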