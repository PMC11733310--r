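# Raw source label -> harmonized class (13-class vocabulary).
# Editable: add one row per raw label appearing in your natural-vegetation
# or crop-parcel source. Types follow from the fixed class->type nesting.
raw	class
# --- natural-vegetation layer labels ---
conifer forest	conifer
conifer woodland	conifer
hardwood forest	hardwood
hardwood woodland	hardwood
shrubland	shrub
chaparral	shrub
sagebrush	shrub
grassland	grassland
annual grassland	grassland
perennial grassland	grassland
herbaceous	herbaceous
wet meadow	herbaceous
desert scrub	desert
desert wash	desert
barren	barren/other
rock	barren/other
dune	barren/other
water	water/wetland
lacustrine	water/wetland
riverine	water/wetland
wetland	water/wetland
marsh	water/wetland
urban	urban
developed	urban
# --- crop-parcel layer labels ---
rice	rice
wild rice	rice
almonds	fruits/nuts/vineyards
walnuts	fruits/nuts/vineyards
pistachios	fruits/nuts/vineyards
grapes	fruits/nuts/vineyards
olives	fruits/nuts/vineyards
citrus	fruits/nuts/vineyards
pears	fruits/nuts/vineyards
peaches	fruits/nuts/vineyards
plums prunes apricots	fruits/nuts/vineyards
corn	row/field crops
tomatoes	row/field crops
wheat	row/field crops
safflower	row/field crops
sunflower	row/field crops
alfalfa	row/field crops
beans	row/field crops
cucurbits	row/field crops
potatoes	row/field crops
onions garlic	row/field crops
cotton	row/field crops
pasture	grassland
mixed pasture	grassland
idle	miscellaneous
fallow	miscellaneous
field margin	miscellaneous
# --- identity rows: already-harmonized labels pass through ---
conifer	conifer
hardwood	hardwood
shrub	shrub
desert	desert
barren/other	barren/other
water/wetland	water/wetland
fruits/nuts/vineyards	fruits/nuts/vineyards
row/field crops	row/field crops
miscellaneous	miscellaneous
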