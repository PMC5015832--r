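food_name,group_index
maize_porridge,1
rice_boiled,1
cassava_gari,1
yam_pounded,1
cowpea_stew,2
soy_cheese,2
groundnut_paste,3
sesame_seeds,3
cow_milk,4
fish_smoked,5
chicken_grilled,5
beef_sauce,5
egg_boiled,6
amaranth_leaves,7
baobab_leaves,7
palm_oil_red,8
mango_ripe,8
papaya,8
okra_fresh,9
tomato_sauce,9
onion_raw,9
orange,10
banana,10
pineapple,10
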