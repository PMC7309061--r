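name,kcal_per_100g
white bread,265
rye bread,259
butter,717
milk,61
yogurt,59
cheese,402
eggs,155
oatmeal,68
rice cooked,130
pasta cooked,158
potatoes boiled,87
chicken breast,165
beef,250
pork,242
salmon,208
apple,52
banana,89
orange,47
carrot,41
tomato,18
cucumber,16
chocolate,546
honey,304
sunflower oil,884
cottage cheese,98
beans cooked,127
soup vegetable,35
herring,217
buckwheat cooked,92
sour cream,193
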