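source_id	target_id	interaction_type	directed	edge_weight
b_01	b_02	binding	FALSE	1
b_01	b_03	binding	FALSE	1
b_01	b_04	binding	FALSE	1
b_01	b_05	binding	FALSE	1
b_01	b_06	binding	FALSE	1
b_02	b_03	binding	FALSE	1
b_02	b_04	binding	FALSE	1
b_02	b_05	binding	FALSE	1
b_02	b_06	binding	FALSE	1
b_03	b_04	binding	FALSE	1
b_03	b_05	binding	FALSE	1
b_03	b_06	binding	FALSE	1
b_04	b_05	binding	FALSE	1
b_04	b_06	binding	FALSE	1
b_05	b_06	binding	FALSE	1
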