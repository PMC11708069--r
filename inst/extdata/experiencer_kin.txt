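# LIVB terms denoting relatives (experiencer = Family_member).
madre
padre
madres
padres
hermano
hermana
hermanos
hermanas
hijo
hija
hijos
hijas
abuelo
abuela
abuelos
abuelas
familiar
familiares
progenitor
progenitores
esposo
esposa
cónyuge
gemelo
gemela
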