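node_id	weight	significance	size	colour_value
a_hub	0.9	0.01	1.375	0.9
a_l1	0.6	0.03	1.25	0.6
a_l4	0.7	0.02	1.2916666666666667	0.7
b_01	-1.1	0.002	1.4583333333333335	-1.1
b_02	-1.4	0.001	1.5833333333333335	-1.4
b_03	-0.9	0.01	1.375	-0.9
b_04	-1.2	0.005	1.5	-1.2
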