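# Contraindication triggers. Columns: pattern <TAB> direction
contraindicación\s+(?:a|para|de)	pre
contraindicacion\s+(?:a|para|de)	pre
contraindicaciones\s+(?:a|para|de)	pre
está\s+contraindicado	post
está\s+contraindicada	post
contraindicado	post
contraindicada	post
contraindicados	post
contraindicadas	post
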