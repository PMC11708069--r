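---
title: "Annotation model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotation model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinspan)
```

`clinspan` annotates Spanish medical text with medical entities,
medication information, temporal expressions, negation/speculation and
contextual attributes. This vignette explains the annotation model, the
tunable parameters, the numerical and design choices behind the
implementation, and what the synthetic test corpus does and does not
demonstrate.

## The document model

A `clin_document` holds the raw and normalized text, sentence and token
segmentation, entities and attributes. All offsets are 0-based,
end-exclusive and counted in Unicode code points — the BRAT standoff
convention — so `.ann` files written by the package load bit-exactly in
the BRAT tool.

Text normalization is a *same-length substitution*: curly quotes become
straight quotes, non-breaking and thin spaces become plain spaces, soft
hyphens and typographic dashes become ASCII hyphens. Because every
replacement maps one code point to one code point, offsets into the
normalized text are valid into the raw text and no offset map is
needed. The substitution table is a packaged, documented choice: there
is no canonical list of "problem characters", so the table collects the
characters that most often break downstream tokenizers and models; it
is a plain named vector and can be replaced per call.

Entities are organised in five layers — `umls`, `temporal`,
`medication`, `misc`, `cues`. Overlap is forbidden *within* a layer but
allowed *across* layers (a Dose inside a procedure phrase, say). One
deliberate exception: a lexicon entry that belongs to several semantic
groups emits co-located entities on the same span, stored in the umls
layer and tolerated by the validator; the package does not attempt
word-sense disambiguation, and a downstream merge policy can prune.
Each entity can carry at most one attribute of a given type.

Tokenization is an injected provider: any function returning sentence
spans and tokens (offsets, lemma, coarse POS) satisfying the documented
contract can be used, e.g. a wrapper around a full morphological
analyser. The packaged default is a dependency-free regex
splitter/tokenizer; its lemma is simply the lowercased surface, which
is sufficient for the folded dictionary lookup described next.

## Dictionary entity recognition

The lexicon is a tab-separated table of entries (lemma, surface
variants, semantic groups, UMLS CUIs, SNOMED CT codes, abbreviation
flag), modelled on medical lexicons with lemma/variant structure.
Matching is greedy left-to-right longest match over token n-grams,
bounded by sentences, trying surface forms before lemma sequences at
equal length (surface is the more specific evidence). Lookup keys are
case-folded with Spanish accents stripped (`á é í ó ú ü`; `ñ` is a
distinct letter and kept) because accents are written inconsistently in
clinical text — but entries flagged as abbreviations are matched
case-sensitively and unfolded, so the route abbreviation *IV* never
fires on the word *iv* and acronyms keep their case significance.
Longest-match is the standard choice for dictionary NER; nothing in the
matched corpus suggested a different strategy, and the matcher is
verified against a brute-force n-gram oracle in the test suite.

Concept normalization filters an entity's codes to a single scheme
(UMLS CUIs or SNOMED CT); unknown surfaces simply yield empty codes.
Sense disambiguation is explicitly out of scope.

## Rule layers

**Temporal expressions.** An editable rule table (pattern, class,
priority) with `<NUM>`/`<TUNIT>` macros covers Date, Duration,
Frequency and Time, plus Age. Spanish number words up to the nineties
are expanded so *dos horas* parses like *2 horas*. Overlapping
candidates are resolved by priority, then span length, then position.
Two choices deserve a note:

* *Age disambiguation.* `N años` is ambiguous between a Duration and an
  age mention. It becomes Age only when an age trigger (*edad*,
  *mayores/menores de*, *de edad*) occurs within a four-token window;
  otherwise it stays Duration. The window of 4 tokens covers the
  attested trigger constructions without reaching into neighbouring
  clauses.
* *pre-/post- expressions* (e.g. *postoperatorio*) are kept as Date by
  default and Time when the head is a time-of-day word, preserving the
  Date/Time distinction rather than a separate merged class.

No calendar-value normalization is attempted: the annotation target is
span + class, not TIMEX values.

**Medication information.** Dose, Concentration and Strength are one
class (Dose): a number — digits with decimal comma or dot, a range
(`10-20 mg`), or a number word — followed by a unit with optional
compound denominators (`mg/kg`, `mg/m²`). Digits may abut the unit
(`125mg`) but number words must be whitespace-separated, so a token
like *UNL* is never parsed as *un* + unit *L*. The percent sign is
deliberately **not** a dose unit: bare percentages belong to
Result_or_Value, and making `%` a dose unit would let Dose swallow
`≥ 50%`. Routes and forms come from editable starter lists in the
style of the public Nomenclátor vocabulary (with plural expansion and
a `vía` prefix rule); all-uppercase route entries are abbreviations.

**Miscellaneous entities.** Result_or_Value requires a comparator
(`<`, `>`, `≤`, `≥`, `=`) before the number — this keeps plain counts
untagged — with an optional unit token. Quantifier_or_Qualifier
combines quantity patterns (*al menos 4*) with a packaged list of
severity/laterality/extent adjectives. When a Result_or_Value span
overlaps a Dose span the Dose wins, so `125 mg` is never double-tagged.
CONC, Food_or_Drink and Observation_or_Finding are lexicon-driven only;
CONC in particular has no pattern definition beyond its lexicon
entries.

**Negation and speculation.** Trigger tables (cue, pseudo-trigger,
termination term; negation or speculation polarity; pre/post direction)
follow the NegEx/ConText design translated to Spanish; the shipped
tables are a starter set, editable as data files. Cue detection takes
the longest trigger at a position, and any cue contained in a
pseudo-trigger match (*no solo*, *sin dificultad*) is suppressed. A
pre-cue scope runs forward from the cue to the earliest of sentence
end, the first termination term (*pero*, *aunque*, ...) or
`max_window` tokens (default 6, the classic NegEx window; whether the
original window or only terminators bound the scope is not documented
anywhere authoritative, so the window is a configurable parameter).
Crucially, the package follows *concept-level* semantics: scopes are
computed internally but never annotated; only entities of the UMLS
layers fully contained in a scope receive `Negated` or `Speculated`.
With several covering scopes the nearest cue wins and negation beats
speculation on ties. Syntax-based scope resolution and double negation
are out of scope.

**Contextual attributes.** Event temporality (History_of,
Family_History_of, Future, Hypothetical) is assigned to disorder,
procedure and physiology entities from trigger tables within an
8-token directional window; the longest trigger wins
(*antecedentes familiares de* beats *antecedentes de*) and precedence
at equal distance is Family_History_of > History_of > Hypothetical >
Future. Because trial texts use the simple future heavily, a
toggleable heuristic treats `-rá`/`-rán` verb forms as Future
triggers; it requires the accented form, so ordinary words ending in
unaccented `-ra` never fire. Hypothetical and Family_History_of are
fully supported in the rule path even where sequence models would lack
training instances for them. Experiencer attributes attach only to
living-being entities found in the packaged patient/kin/role lists;
unlisted LIVB terms stay bare rather than defaulting to Patient.
Contraindication triggers mark CHEM/PROC entities in a 6-token window,
and a negation word immediately before the trigger (*sin
contraindicación a*) suppresses the attribute — without this guard the
meaning would invert. Age-denoting LIVB terms (*adultos*, *niños*)
receive the Age attribute only; they do not additionally produce an
Age temporal entity, keeping the temporal layer to true temporal
expressions.

## Model backend and hybrid merge

The sequence-labeling backend is a contract, not a dependency: an
adapter receives sentences as token lists and must return exactly one
BIO label and one confidence per input token, handling any subword
splitting internally by the first-subword convention. BIO decoding
repairs invalid transitions (`I-X` after `O` or after another class
becomes `B-X`). The hybrid merge (default `model_first` with code
enrichment) collapses span- and label-identical pairs onto the model
entity carrying the dictionary's codes, keeps the model entity on
overlap conflicts, and always retains dictionary-only groups (ACTI).
The merge policy is configurable precisely because no authoritative
conflict-resolution rule exists for the dictionary/model combination.
All tests run against a deterministic mock adapter; real pretrained
adapters are optional extras behind the same contract, which keeps the
test suite offline and byte-reproducible.

## Formats

BIO output is the two-column CoNLL dialect (token TAB label, blank line
between sentences). BRAT output uses binary attribute lines
(`A1\tNegated T2`) matching the boolean attribute scheme, and
normalization lines (`N1\tReference T2 UMLS:C0338237\t...`). The JSON
schema (`doc_id`, `text`, `entities`, `attributes` with stable key
order) is normative for this package. Round-trips are lossless modulo
identifier renumbering; discontinuous entities are not supported and
would be dropped with a logged count during BIO conversion.

## Evaluation conventions

Scoring is entity-level. Strict: exact (start, end, label). Relaxed:
same label with at least one character of overlap, matched one-to-one
greedily by descending overlap (ties by smaller reference start) — no
standard definition of relaxed matching exists, so this definition is
normative here. Zero denominators yield P = R = F1 = 0, matching
common sequence-evaluation behaviour. Micro-averages sum TP/FP/FN over
labels, the appropriate choice under heavy class imbalance. The
inter-annotator agreement measure is the pairwise F-measure, symmetric
in F1 under annotator swap. Corpus means are reported floored at two
decimals, the convention under which 86 389 entities over 1200 texts
give 71.99 per text and 16 590 attributes give 13.82. Attribute
scoring treats (entity span, attribute type) pairs as the unit.

## The synthetic corpus, and what the tests show

The fixtures module generates a toy lexicon (every semantic group
represented, a multiword disorder, a CUI-sharing Route synonym pair
*intravenoso*/*IV*, an ACTI entry) and a gold-annotated corpus from a
template grammar. Each document draws one sentence from each of six
template pools — negation/speculation, experiencer/contraindication,
event temporality, temporal, medication, miscellaneous — so every
layer is populated; the worked sentences quoted throughout the
documentation are fixed templates. Templates carry their exact gold
entities and attributes by construction, and the central end-to-end
test requires the full rule pipeline to reproduce a 50-document corpus
at strict micro F1 = 1.0.

This is a *self-consistency* guarantee: it shows the pipeline, the
data model, the offsets and the serialization are internally coherent,
and it pins down every documented behaviour. It does **not** estimate
real-world accuracy: the generator uses only toy-lexicon vocabulary and
trigger-table cues, its sentence structure is far simpler than real
eligibility criteria, and it contains no out-of-vocabulary mentions,
typos, ambiguous cues or discontinuous entities. Scores on real
corpora are expected to be substantially below 1 and must be measured
against real gold annotations. The synonym-replacement augmentation
(surfaces swapped for CUI-sharing variants, offsets recomputed)
supports data-augmentation experiments but, again, only emulates the
mechanism, not corpus statistics.

Problem sizes used by the shipped checks — 50 documents for the
end-to-end test, 100 for round-trips, 200 randomized instances per
oracle-equivalence property — were chosen as the smallest sets that
exercise all template combinations several times over; all are
deterministic under fixed seeds.

## Known limitations

* No word-sense disambiguation of normalization codes; multi-group
  lexicon entries stay ambiguous.
* No temporal relation extraction, calendar normalization or
  document-time anchoring.
* No syntax-based negation scope; window/terminator scopes mislabel
  long-range dependencies.
* Discontinuous entities are unsupported.
* The packaged trigger tables and term lists are starter sets meant to
  be edited for a concrete deployment; the toy lexicon is a fixture,
  not a clinical resource.
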