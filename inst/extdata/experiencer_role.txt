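# LIVB terms denoting clinical/research roles (experiencer = Other).
investigador
investigadora
investigadores
investigadoras
médico
médica
médicos
médicas
enfermero
enfermera
enfermeros
enfermeras
cirujano
cirujana
evaluador
evaluadora
evaluadores
monitor
monitores
facultativo
facultativos
personal sanitario
donante
donantes
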