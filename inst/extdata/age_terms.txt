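# LIVB terms that also convey age information (Age attribute).
adulto
adulta
adultos
adultas
adolescente
adolescentes
niño
niña
niños
niñas
anciano
anciana
ancianos
ancianas
lactante
lactantes
neonato
neonatos
recién nacido
recién nacidos
joven
jóvenes
menor
menores
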