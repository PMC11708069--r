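# Administration routes (Nomenclátor-style starter list).
# All-uppercase entries are abbreviations, matched case-sensitively.
oral
orales
intravenoso
intravenosa
intravenosos
intravenosas
subcutáneo
subcutánea
intramuscular
tópico
tópica
inhalado
inhalada
inhalatoria
sublingual
rectal
nasal
oftálmico
oftálmica
transdérmico
transdérmica
parenteral
intratecal
epidural
IV
IM
SC
VO
SL
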