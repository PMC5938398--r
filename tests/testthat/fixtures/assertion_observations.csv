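observation_id,subject_id,genus,species,latitude,longitude,date,trait_id,value_kind,lower,upper,source,source_record_id
FIX001,plant_01,Helianthus,annuus,29.6,-82.3,2015-06-01,unfolded_true_leaf_presence,count,10,20,other,FIX001
FIX002,plant_02,Helianthus,annuus,29.6,-82.3,2015-02-01,unfolded_true_leaf_presence,count,0,0,other,FIX002
FIX003,plant_03,Acer,rubrum,45.1,-93.2,2015-03-15,dormant_leaf_bud_presence,count,1,1,other,FIX003
FIX004,plant_04,Acer,rubrum,45.1,-93.2,2015-07-01,leaf_bud_presence,count,0,0,other,FIX004
FIX005,plant_05,Acer,rubrum,45.1,-93.2,2015-04-20,breaking_leaf_bud_presence,count,2,5,other,FIX005
FIX006,plant_06,Quercus,robur,48.2,16.4,2015-06-15,true_leaf_presence,percent,80,80,other,FIX006
FIX007,plant_07,Quercus,robur,48.2,16.4,2015-01-10,true_leaf_presence,percent,0,0,other,FIX007
FIX008,plant_08,Syringa,vulgaris,59.3,18.1,2015-05-05,flower_presence,count,0,7,other,FIX008
FIX009,plant_09,Syringa,vulgaris,59.3,18.1,2015-05-20,pollen_releasing_flower_presence,percent,12.5,50,other,FIX009
FIX010,plant_10,Syringa,vulgaris,59.3,18.1,2015-09-01,flower_presence,count,0,0,other,FIX010
FIX011,plant_11,Pinus,sylvestris,60.2,24.9,2015-08-10,ripe_seed_cone_presence,count,3,3,other,FIX011
FIX012,plant_12,Pinus,sylvestris,60.2,24.9,2015-02-20,cone_presence,count,0,0,other,FIX012
FIX013,plant_13,Acer,saccharum,44.0,-71.5,2015-10-12,abscised_true_leaf_presence,count,4,10,other,FIX013
FIX014,plant_14,Acer,saccharum,44.0,-71.5,2015-06-20,abscised_true_leaf_presence,count,0,0,other,FIX014
FIX015,plant_15,Malus,domestica,52.5,13.4,2015-07-18,fruit_presence,percent,0,30,other,FIX015
FIX016,plant_16,Malus,domestica,52.5,13.4,2015-09-25,ripe_fruit_presence,count,1,,other,FIX016
FIX017,plant_17,Pinus,sylvestris,60.2,24.9,2015-03-05,seed_cone_presence,count,0,0,other,FIX017
FIX018,plant_18,Quercus,robur,48.2,16.4,2015-04-02,swelling_leaf_bud_presence,count,7,12,other,FIX018
FIX019,plant_19,Quercus,robur,48.2,16.4,2015-10-01,senescing_true_leaf_presence,percent,5,25,other,FIX019
FIX020,plant_20,Syringa,vulgaris,59.3,18.1,2015-11-02,open_flower_presence,count,0,0,other,FIX020
FIX021,plant_21,Acer,platanoides,50.1,8.7,2015-06-30,true_leaf_presence,count,10,20,other,FIX021
FIX021,plant_21,Acer,platanoides,50.1,8.7,2015-06-30,flower_presence,count,0,0,other,FIX021
FIX022,plant_22,Acer,platanoides,50.1,8.7,2015-01-25,unfolding_true_leaf_presence,count,0,0,other,FIX022
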