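food_group,target,lower,upper,direction,eli_direction,wish_curve,wish_breakpoints,eli_bands
whole_grains,232,0,232,encouraged,emphasised,ramp_up,232,58;116;232
vegetables,300,200,600,encouraged,emphasised,ramp_up,300,75;150;300
fruits,200,100,300,encouraged,emphasised,ramp_up,200,50;100;200
tubers,50,0,100,limited,limited,,,50;100;200
legumes,75,0,150,encouraged,emphasised,ramp_up,75,18.75;37.5;75
nuts,50,0,75,encouraged,emphasised,ramp_up,50,12.5;25;50
unsaturated_oils,40,20,80,encouraged,emphasised,ramp_up,40,10;20;40
dairy,250,0,500,encouraged,limited,plateau_range,0;0;250;500,250;500;1000
red_meat,28,0,28,limited,,ramp_down,28;112,
red_meat_beef_lamb,14,0,14,limited,limited,,,14;28;56
red_meat_pork,14,0,14,limited,limited,,,14;28;56
poultry,29,0,58,limited,limited,plateau_range,0;0;58;116,29;58;116
eggs,13,0,25,limited,limited,plateau_range,0;0;25;50,13;26;52
fish,28,0,100,encouraged,emphasised,ramp_up,28,7;14;28
saturated_fats,11.8,0,11.8,limited,,ramp_down,11.8;47.2,
added_sugars,31,0,31,limited,limited,ramp_down,31;124,31;62;124
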