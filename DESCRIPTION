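Package: clinspan
Title: Semantic Annotation of Spanish Medical Text
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A hybrid annotation toolkit for Spanish clinical and
    clinical-trial text. Combines dictionary-based named entity
    recognition with UMLS/SNOMED CT concept normalization, rule-based
    tagging of temporal expressions (Date, Duration, Frequency, Time,
    Age), medication information (Dose, Route, Form) and miscellaneous
    clinical entities, NegEx/ConText-style negation and speculation
    detection at the concept level, and temporality/experiencer/
    contraindication attributes. Supports a pluggable token-classification
    backend merged with the dictionary output, BIO/BRAT/JSON interchange,
    and strict and relaxed entity-level evaluation with inter-annotator
    agreement F-measure.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
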