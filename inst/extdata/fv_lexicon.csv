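name_pattern,eligibility_class,form_default
coconut (milk|cream|oil|fat),fruit,other_processed
coconut,fruit,fresh_or_whole
(chickpea|pea|lentil|bean|lupin) (flour|protein|isolate),pulse,powder
soy(a)? (protein|isolate|flour),pulse,powder
tofu,pulse,other_processed
chickpea,pulse,fresh_or_whole
lentil,pulse,fresh_or_whole
(^| )pea( |s|$),pulse,fresh_or_whole
bean,pulse,fresh_or_whole
lupin,pulse,fresh_or_whole
soy(a)?,pulse,other_processed
almond (flour|powder),nut,powder
(almond|cashew|hazelnut|walnut|peanut|pistachio) (paste|butter),nut,fresh_or_whole
walnut oil,eligible_oil,oil
almond,nut,fresh_or_whole
cashew,nut,fresh_or_whole
hazelnut,nut,fresh_or_whole
walnut,nut,fresh_or_whole
peanut,nut,fresh_or_whole
(rapeseed|canola) oil,eligible_oil,oil
olive oil,eligible_oil,oil
olive,fruit,fresh_or_whole
(sunflower|palm|shea) (oil|fat),other,oil
tomato (paste|concentrate|powder),vegetable,concentrate
tomato,vegetable,fresh_or_whole
onion powder,vegetable,powder
onion,vegetable,fresh_or_whole
garlic powder,vegetable,powder
garlic,vegetable,fresh_or_whole
carrot,vegetable,fresh_or_whole
beetroot,vegetable,fresh_or_whole
mushroom,vegetable,fresh_or_whole
spinach,vegetable,fresh_or_whole
(apple|orange|lemon) juice concentrate,fruit,concentrate
(apple|orange|lemon) juice,fruit,juice
date,fruit,dried
raisin,fruit,dried
candied,fruit,candied
(wheat|rice|oat|corn|maize) (flour|starch|gluten),other,flour
(wheat|rice|oat|spelt|barley|millet) ,other,other_processed
seitan,other,other_processed
starch,other,flour
water,other,other_processed
salt,other,other_processed
sugar,other,other_processed
yeast,other,other_processed
thickener,other,other_processed
emulsifier,other,other_processed
flavouring,other,other_processed
vinegar,other,other_processed
spice,other,other_processed
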