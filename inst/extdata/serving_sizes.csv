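unit,grams_per_unit,note
fruit_g_per_cupeq,150,grams of fruit per cup-equivalent
veg_g_per_cupeq,150,grams of vegetables per cup-equivalent
dairy_g_per_cupeq,245,grams of dairy per cup-equivalent
seafood_plant_g_per_cupeq,60,grams of seafood or plant protein per cup-equivalent
grain_g_per_ozeq,28.35,grams of grain product per oz-equivalent
lean_protein_g_per_ozeq,28.35,grams of lean protein food per oz-equivalent
veg_g_per_serving,80,grams of vegetables per serving
fruit_g_per_serving,120,grams of fruit per serving
nuts_g_per_serving,28,grams of nuts or seeds per serving
legume_g_per_serving,100,grams of cooked legumes per serving
meat_g_per_serving,85,grams of red or processed meat per serving
ssb_ml_per_serving,240,millilitres of sweetened beverage per serving
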