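node_id	weight	significance	size	colour_value
a_hub	2	0.001	1.8333333333333335	2
a_l1	1.6	0.004	1.6666666666666667	1.6
a_l2	1.4	0.01	1.5833333333333335	1.4
a_l3	-1.2	0.02	1.5	-1.2
a_l4	1.8	0.003	1.75	1.8
a_l5	1.5	0.008	1.625	1.5
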