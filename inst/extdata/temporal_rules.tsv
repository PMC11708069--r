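# HeidelTime-inspired starter rules for Spanish temporal expressions.
# Columns: pattern <TAB> class <TAB> priority
# Macros: <NUM> number (digits or Spanish number word), <TUNIT> time unit.
# If a pattern has a capture group 1, the annotated span is the group.
# Patterns are matched case-insensitively with word boundaries added.
cada\s+<NUM>\s+<TUNIT>	Frequency	30
cada\s+<TUNIT>	Frequency	30
<NUM>\s+(?:vez|veces)\s+(?:al|por)\s+(?:día|dia|semana|mes|año|ano|hora)	Frequency	30
a\s+diario	Frequency	30
semanalmente	Frequency	30
diariamente	Frequency	30
mensualmente	Frequency	30
anualmente	Frequency	30
quincenalmente	Frequency	30
durante\s+(<NUM>\s+<TUNIT>)	Duration	20
durante\s+(?:el|la|los|las)\s+(?:primer(?:os|as)?|últim(?:os|as)?)?\s*(<NUM>\s+<TUNIT>)	Duration	20
<NUM>\s+años\s+de\s+edad	Age	40
<NUM>\s+<TUNIT>	Duration	15
(?:por\s+la\s+|de\s+la\s+|esta\s+)?(noche|tarde|madrugada|mediodía|mediodia|amanecer|anochecer)	Time	20
(?:por\s+la\s+|de\s+la\s+|esta\s+)(mañana)	Time	20
(?:pre|post)[-\s]?(?:noche|tarde|madrugada)	Time	18
(?:pre|post)[-\s]?(?:operatori[oa]s?|quirúrgic[oa]s?|quirurgic[oa]s?|tratamiento|intervención|intervencion|parto|menopáusic[oa]s?|menopausic[oa]s?|natal(?:es)?)	Date	18
(?:19|20)\d{2}	Date	12
\d{1,2}/\d{1,2}/\d{2,4}	Date	12
(?:<NUM>\s+de\s+)?(?:enero|febrero|marzo|abril|mayo|junio|julio|agosto|septiembre|octubre|noviembre|diciembre)(?:\s+de\s+(?:19|20)\d{2})?	Date	12
hoy|ayer|anteayer|actualmente	Date	10
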