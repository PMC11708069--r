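# Qualifier adjectives (severity, laterality, extent); plural variants are
# expanded automatically at load.
grave
leve
severo
severa
moderado
moderada
agudo
aguda
crónico
crónica
bilateral
unilateral
izquierdo
izquierda
derecho
derecha
persistente
recurrente
progresivo
progresiva
generalizado
generalizada
localizado
localizada
intenso
intensa
refractario
refractaria
avanzado
avanzada
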