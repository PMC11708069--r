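# Negation/speculation triggers (NegEx/ConText translated to Spanish).
# Columns: pattern <TAB> polarity <TAB> direction <TAB> kind
# polarity: negation|speculation ("-" for termination terms)
# direction: pre (cue precedes scope) | post (scope precedes cue)
# kind: cue | pseudo | termination
no	negation	pre	cue
sin	negation	pre	cue
ausencia\s+de	negation	pre	cue
niega	negation	pre	cue
negativo\s+para	negation	pre	cue
descartar	negation	pre	cue
se\s+descartó	negation	pre	cue
se\s+descarta	negation	pre	cue
tampoco	negation	pre	cue
libre\s+de	negation	pre	cue
exento\s+de	negation	pre	cue
ningún	negation	pre	cue
ninguna	negation	pre	cue
descartado	negation	post	cue
descartada	negation	post	cue
posible	speculation	pre	cue
posibles	speculation	pre	cue
probable	speculation	pre	cue
probables	speculation	pre	cue
sospecha\s+de	speculation	pre	cue
podría	speculation	pre	cue
podrían	speculation	pre	cue
puede\s+que	speculation	pre	cue
sugiere	speculation	pre	cue
sugestivo\s+de	speculation	pre	cue
compatible\s+con	speculation	pre	cue
no\s+solo	negation	pre	pseudo
no\s+sólo	negation	pre	pseudo
no\s+obstante	negation	pre	pseudo
sin\s+embargo	negation	pre	pseudo
sin\s+dificultad	negation	pre	pseudo
no\s+se\s+puede\s+descartar	speculation	pre	pseudo
pero	-	-	termination
aunque	-	-	termination
excepto	-	-	termination
salvo	-	-	termination
aparte\s+de	-	-	termination
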