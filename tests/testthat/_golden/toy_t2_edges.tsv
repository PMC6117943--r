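source_id	target_id	interaction_type	directed	edge_weight
a_hub	a_l1	activation	TRUE	1
a_hub	a_l4	activation	TRUE	1
b_01	b_02	binding	FALSE	1
b_01	b_03	binding	FALSE	1
b_01	b_04	binding	FALSE	1
b_02	b_03	binding	FALSE	1
b_02	b_04	binding	FALSE	1
b_03	b_04	binding	FALSE	1
a_hub	b_01	inhibition	TRUE	1
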