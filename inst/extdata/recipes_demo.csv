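dish_id,food_group,proportion,gated
ham_vegetable_sandwich_black_bread,red_meat_pork,0.20,FALSE
ham_vegetable_sandwich_black_bread,vegetables,0.10,FALSE
ham_vegetable_sandwich_black_bread,whole_grains,0.50,FALSE
beef_vegetable_stew,red_meat_beef_lamb,0.30,FALSE
beef_vegetable_stew,vegetables,0.35,FALSE
beef_vegetable_stew,tubers,0.20,FALSE
pork_goulash,red_meat_pork,0.35,FALSE
pork_goulash,vegetables,0.25,FALSE
pork_goulash,tubers,0.15,FALSE
margherita_pizza,dairy,0.20,FALSE
margherita_pizza,vegetables,0.15,FALSE
margherita_pizza,unsaturated_oils,0.05,FALSE
chicken_curry_rice,poultry,0.30,FALSE
chicken_curry_rice,vegetables,0.20,FALSE
chicken_curry_rice,dairy,0.05,FALSE
chicken_curry_rice,unsaturated_oils,0.05,FALSE
fish_pie,fish,0.35,FALSE
fish_pie,tubers,0.30,FALSE
fish_pie,dairy,0.10,FALSE
lentil_soup,legumes,0.40,FALSE
lentil_soup,vegetables,0.25,FALSE
lentil_soup,unsaturated_oils,0.03,FALSE
sweetened_wholegrain_cereal,whole_grains,0.70,TRUE
sweetened_wholegrain_cereal,added_sugars,0.25,FALSE
fruit_yogurt_sweetened,dairy,0.70,FALSE
fruit_yogurt_sweetened,added_sugars,0.12,FALSE
fruit_yogurt_sweetened,fruits,0.10,TRUE
cheese_omelette,eggs,0.60,FALSE
cheese_omelette,dairy,0.25,FALSE
cheese_omelette,saturated_fats,0.05,FALSE
vegetable_quiche,eggs,0.25,FALSE
vegetable_quiche,vegetables,0.30,FALSE
vegetable_quiche,dairy,0.15,FALSE
vegetable_quiche,saturated_fats,0.10,FALSE
nut_granola_bar_sweetened,nuts,0.30,TRUE
nut_granola_bar_sweetened,whole_grains,0.35,TRUE
nut_granola_bar_sweetened,added_sugars,0.30,FALSE
bean_chili_con_carne,legumes,0.25,FALSE
bean_chili_con_carne,red_meat_beef_lamb,0.25,FALSE
bean_chili_con_carne,vegetables,0.30,FALSE
salmon_salad_olive_oil,fish,0.40,FALSE
salmon_salad_olive_oil,vegetables,0.45,FALSE
salmon_salad_olive_oil,unsaturated_oils,0.10,FALSE
potato_gratin,tubers,0.55,FALSE
potato_gratin,dairy,0.25,FALSE
potato_gratin,saturated_fats,0.08,FALSE
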