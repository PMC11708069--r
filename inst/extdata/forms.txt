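# Dosage forms (Nomenclátor-style starter list); plural variants are
# expanded automatically at load.
píldora
comprimido
cápsula
tableta
jarabe
solución
suspensión
pomada
crema
parche
inyección
supositorio
aerosol
gel
polvo
ampolla
vial
sobre
gragea
óvulo
colirio
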