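source_id	target_id	interaction_type	directed	edge_weight
a_hub	a_l1	activation	TRUE	1
a_hub	a_l2	activation	TRUE	1
a_hub	a_l3	inhibition	TRUE	1
a_hub	a_l4	activation	TRUE	1
a_hub	a_l5	inhibition	TRUE	1
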