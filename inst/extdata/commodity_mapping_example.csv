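commodity_code,commodity_name,group_id
2763,Pelagic Fish,pelagic_fish
2762,Demersal Fish,demersal_fish
2761,Freshwater Fish,freshwater_fish
2764,"Marine Fish, Other",marine_fish_other
2782,"Fish, Liver Oil",fish_liver_oil
2949,Eggs,eggs
2731,Bovine Meat,bovine_meat
2733,Pigmeat,pig_meat
2734,Poultry Meat,poultry_meat
2732,Mutton & Goat Meat,mutton_goat_meat
2737,"Fats, Animals, Raw",animal_fats
2740,"Butter, Ghee",butter
2948,Milk - Excluding Butter,milk
2511,Wheat and products,wheat
2514,Maize and products,maize
2805,Rice (Milled Equivalent),rice
2914,Vegetable Oils,vegetable_oils
2918,Vegetables,vegetables
2919,Fruits - Excluding Wine,fruits
2911,Pulses,pulses
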