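# LIVB terms denoting the patient (experiencer = Patient).
paciente
pacientes
enfermo
enferma
enfermos
enfermas
sujeto
sujetos
participante
participantes
voluntario
voluntaria
voluntarios
voluntarias
caso índice
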