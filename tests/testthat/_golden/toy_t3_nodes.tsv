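node_id	weight	significance	size	colour_value
b_01	-2.1	0.001	1.875	-2.1
b_02	-2.4	0.001	2	-2.4
b_03	-1.8	0.002	1.75	-1.8
b_04	-2	0.001	1.8333333333333335	-2
b_05	-1.6	0.004	1.6666666666666667	-1.6
b_06	-1.9	0.003	1.7916666666666665	-1.9
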