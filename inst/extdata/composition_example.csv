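group_id,group_name,vitd3_ug_per_100g,ohd3_ug_per_100g,source
pelagic_fish,Pelagic fish,8.0,0.30,illustrative (synthetic values)
demersal_fish,Demersal fish,3.0,0.05,illustrative (synthetic values)
freshwater_fish,Freshwater fish,5.0,0.10,illustrative (synthetic values)
marine_fish_other,"Marine fish, other",4.0,0.10,illustrative (synthetic values)
fish_liver_oil,Fish liver oil,210.0,0.00,illustrative (synthetic values)
eggs,Eggs,3.2,0.35,illustrative (synthetic values)
bovine_meat,Bovine meat,0.5,0.15,illustrative (synthetic values)
pig_meat,Pig meat,0.7,0.10,illustrative (synthetic values)
poultry_meat,Poultry meat,0.3,0.05,illustrative (synthetic values)
mutton_goat_meat,Mutton and goat meat,0.4,0.10,illustrative (synthetic values)
animal_fats,Raw animal fats,1.1,0.20,illustrative (synthetic values)
butter,Butter and ghee,1.0,0.15,illustrative (synthetic values)
milk,Milk excluding butter,0.03,0.01,illustrative (synthetic values)
wheat,Wheat and products,0.0,0.00,illustrative (synthetic values)
maize,Maize and products,0.0,0.00,illustrative (synthetic values)
rice,Rice and products,0.0,0.00,illustrative (synthetic values)
vegetable_oils,Vegetable oils,0.0,0.00,illustrative (synthetic values)
vegetables,Vegetables,0.0,0.00,illustrative (synthetic values)
fruits,Fruits,0.0,0.00,illustrative (synthetic values)
pulses,Pulses,0.0,0.00,illustrative (synthetic values)
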