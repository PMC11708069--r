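# clinspan

Semantic annotation of Spanish medical text: a hybrid (lexicon + rules +
pluggable sequence-labeling backend) named-entity annotator for clinical
trial announcements, clinical cases and similar documents, written for
clinical NLP practitioners who need structured, normalized annotations
out of raw Spanish text.

## What it does

Given a UTF-8 text, `clinspan` runs a three-stage pipeline:

1. **Pre-processing and UMLS entity recognition.** Same-length character
   normalization (offsets never shift), sentence splitting and
   tokenization through an injectable provider, then dictionary-based
   recognition of UMLS semantic groups (ANAT, CHEM, DISO, PROC, DEVI,
   GENE, PHYS, LIVB, ACTI) with concept normalization to UMLS CUIs or
   SNOMED CT codes. A token-classification model can replace or be
   merged with the dictionary (`backend = "model"` / `"hybrid"`); ACTI
   entities are recognised only by the dictionary and survive the merge.
2. **Rule layers**, each independently toggleable:
   * temporal expressions — Date, Duration, Frequency, Time, plus Age
     (`mayores de 18 años`);
   * medication information — Dose (`125 mg`, `5 mg/kg`), Route
     (`intravenoso`, `IV`, `vía oral`), Form (`píldora`, `comprimidos`);
   * miscellaneous clinical entities — Result_or_Value (`< 3 UNL`),
     Quantifier_or_Qualifier (`al menos 4`, `grave`), and the
     lexicon-driven CONC, Food_or_Drink, Observation_or_Finding classes;
   * negation/speculation cues (NegEx/ConText translated to Spanish)
     with **concept-level** attribute assignment: entities inside a
     cue's scope receive `Negated`/`Speculated`; scopes themselves are
     never emitted as annotations;
   * ConText-style attributes — `History_of`, `Family_History_of`,
     `Future`, `Hypothetical`, experiencer (`Patient`, `Family_member`,
     `Other`), `Contraindicated` and `Age` on age-denoting living
     beings.
3. **Serialization** to JSON or BRAT standoff (`.txt`/`.ann`), plus
   CoNLL-style BIO conversion for sequence-labeling tooling.

Evaluation utilities implement entity-level scoring with

    P = TP / (TP + FP),  R = TP / (TP + FN),  F1 = 2PR / (P + R)

under a *strict* criterion (exact span and class) or a *relaxed* one
(same class, at least one character of overlap, one-to-one greedy
pairing), micro-averaged over classes, along with the pairwise
F-measure used for inter-annotator agreement and corpus statistics.

## Worked example

```r
library(clinspan)
lex <- toy_lexicon()
doc <- annotate("Los pacientes no habían recibido tratamiento antibiótico.",
                lexicon = lex)
doc
#> <clin_document 'doc': 57 chars, 1 sentences, 3 entities, 2 attributes>
#>   entities: LIVB=1 Neg_cue=1 PROC=1
doc$entities[, c("id", "label", "start", "end", "surface", "codes")]
#>   id   label start end                 surface         codes
#> 1 E1    LIVB     4  13               pacientes UMLS:C0030705
#> 2 E2    PROC    33  56 tratamiento antibiótico UMLS:C0338237
#> 3 E3 Neg_cue    14  16                      no
doc$attributes
#>   id    type target
#> 1 A1 Negated     E2
#> 2 A2 Patient     E1
```

The negation cue `no` is annotated, the concept *tratamiento
antibiótico* is `Negated` (the patients are not), the patients are the
`Patient` experiencer, and both dictionary entities carry their UMLS
CUIs. `write_brat(doc, "ej")` emits the same analysis as BRAT standoff:

```
T1	LIVB 4 13	pacientes
T2	PROC 33 56	tratamiento antibiótico
T3	Neg_cue 14 16	no
A1	Negated T2
A2	Patient T1
N1	Reference T1 UMLS:C0030705	pacientes
N2	Reference T2 UMLS:C0338237	tratamiento antibiótico
```

A command-line front end is installed as `exec/clinspan`:

```sh
Rscript exec/clinspan input_dir --out-dir out --format ann --no-misc
```

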