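source_dialect,source_code,trait_id,value_rule
status,leaves,true_leaf_presence,status_to_range
status,flowers,flower_presence,status_to_range
status,senescing_leaves,senescing_true_leaf_presence,status_to_range
event,BBCH11,true_leaf_presence,event_onset
event,BBCH60,flower_presence,event_onset
event,BBCH99,,excluded_agricultural
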