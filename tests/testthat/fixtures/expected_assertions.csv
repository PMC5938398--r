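observation_id,class_id
FIX001,true_leaf_present
FIX001,unfolded_true_leaf_present
FIX002,unfolded_true_leaf_absent
FIX003,dormant_leaf_bud_present
FIX003,leaf_bud_present
FIX004,breaking_leaf_bud_absent
FIX004,dormant_leaf_bud_absent
FIX004,leaf_bud_absent
FIX004,nondormant_leaf_bud_absent
FIX004,swelling_leaf_bud_absent
FIX005,breaking_leaf_bud_present
FIX005,leaf_bud_present
FIX005,nondormant_leaf_bud_present
FIX005,true_leaf_present
FIX005,unfolding_true_leaf_present
FIX006,true_leaf_present
FIX007,breaking_leaf_bud_absent
FIX007,expanding_true_leaf_absent
FIX007,senescing_true_leaf_absent
FIX007,true_leaf_absent
FIX007,unfolded_true_leaf_absent
FIX007,unfolding_true_leaf_absent
FIX009,flower_present
FIX009,open_flower_present
FIX009,pollen_releasing_flower_present
FIX010,flower_absent
FIX010,open_flower_absent
FIX010,pollen_releasing_flower_absent
FIX010,senesced_flower_absent
FIX011,cone_present
FIX011,ripe_seed_cone_present
FIX011,seed_cone_present
FIX012,cone_absent
FIX012,pollen_cone_absent
FIX012,ripe_seed_cone_absent
FIX012,seed_cone_absent
FIX013,abscised_true_leaf_present
FIX014,abscised_true_leaf_absent
FIX016,fruit_present
FIX016,ripe_fruit_present
FIX017,ripe_seed_cone_absent
FIX017,seed_cone_absent
FIX018,leaf_bud_present
FIX018,nondormant_leaf_bud_present
FIX018,swelling_leaf_bud_present
FIX019,senescing_true_leaf_present
FIX019,true_leaf_present
FIX020,open_flower_absent
FIX020,pollen_releasing_flower_absent
FIX021,flower_absent
FIX021,open_flower_absent
FIX021,pollen_releasing_flower_absent
FIX021,senesced_flower_absent
FIX021,true_leaf_present
FIX022,breaking_leaf_bud_absent
FIX022,unfolding_true_leaf_absent
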