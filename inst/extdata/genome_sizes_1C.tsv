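crop	pg_1C	source
soy	1.13	method description
maize	2.725	method description
canola	1.15	method description
cotton	2.33	standard plant 1C value
rice	0.43	standard plant 1C value
sugar beet	0.757	standard plant 1C value
potato	0.87	standard plant 1C value
wheat	16.93	standard plant 1C value
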