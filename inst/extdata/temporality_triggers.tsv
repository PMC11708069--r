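# Event-temporality triggers (ConText-style, adapted to Spanish).
# Columns: pattern <TAB> attribute <TAB> direction
antecedentes\s+familiares\s+de	Family_History_of	pre
antecedente\s+familiar\s+de	Family_History_of	pre
historia\s+familiar\s+de	Family_History_of	pre
antecedentes\s+de	History_of	pre
antecedente\s+de	History_of	pre
antecedentes\s+personales\s+de	History_of	pre
historia\s+de	History_of	pre
historial\s+de	History_of	pre
previamente\s+tratado\s+con	History_of	pre
en\s+caso\s+de	Hypothetical	pre
si	Hypothetical	pre
en\s+el\s+supuesto\s+de	Hypothetical	pre
ante\s+la\s+sospecha\s+de	Hypothetical	pre
se\s+prevé	Future	pre
está\s+previsto	Future	pre
está\s+prevista	Future	pre
próximamente	Future	pre
posteriormente\s+se	Future	pre
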