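# Dose / concentration / strength units (one per line).
# Percent is deliberately absent: bare percentages belong to Result_or_Value.
mg
g
kg
mcg
µg
ug
ng
ml
mL
l
L
dl
dL
cc
UI
U
mEq
mmol
mol
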