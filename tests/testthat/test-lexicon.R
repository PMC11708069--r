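write_lex <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("lemma\tvariants\tgroups\tcuis\tsnomed\tis_abbrev", rows), path)
  path
}

test_that("lexicon loading indexes rows and merges duplicates", {
  lex <- load_lexicon(write_lex(c(
    "fiebre\t\tDISO\tC0015967\t386661006\t0",
    "dolor\tdolores\tDISO\tC0030193\t\t0")))
  expect_length(lex$entries, 2L)

  merged <- load_lexicon(write_lex(c(
    "fiebre\t\tDISO\tC0015967\t\t0",
    "fiebre\t\tDISO\tC0239999\t386661006\t0")))
  expect_length(merged$entries, 1L)
  expect_setequal(merged$entries[[1]]$cuis, c("C0015967", "C0239999"))

  expect_error(load_lexicon(write_lex("mal\t\tDISO\tX123\t\t0")),
               "malformed CUI")
  expect_error(load_lexicon(write_lex("sin_grupo\t\t\tC0000001\t\t0")),
               "no groups")
})

test_that("folding lowercases and strips accents; abbreviations stay exact", {
  expect_identical(fold("Diabetes"), "diabetes")
  expect_identical(fold("FÁRMACO"), "farmaco")
  expect_identical(fold("año"), "año")  # ñ is a distinct letter, kept
  lex <- test_lexicon()
  doc <- mk_doc("metotrexato IV y metotrexato iv")
  ents <- match_entities(doc, lex)
  expect_identical(ents$label[ents$surface == "IV"], "Route")
  expect_false("iv" %in% ents$surface)  # abbreviations are case-sensitive
})

test_that("matching is greedy longest and honours group exclusion", {
  lex <- test_lexicon()
  doc <- mk_doc("paciente con diabetes")
  ents <- match_entities(doc, lex)
  expect_identical(ents$surface[ents$label == "DISO"], "diabetes")

  doc2 <- mk_doc("diabetes mellitus tipo 2")
  ents2 <- match_entities(doc2, lex)
  expect_identical(ents2$surface[ents2$label == "DISO"], "diabetes mellitus")

  doc3 <- mk_doc("Programa de ejercicio físico y fiebre")
  all_groups <- match_entities(doc3, lex)
  expect_true("ACTI" %in% all_groups$label)
  no_acti <- match_entities(doc3, lex, excluded_groups = "ACTI")
  expect_false("ACTI" %in% no_acti$label)
  # excluding ACTI left the other groups untouched
  expect_identical(entity_key(no_acti),
                   entity_key(all_groups[all_groups$label != "ACTI", ]))

  expect_error(match_entities(clin_document("hola"), lex), "segmented")
})

test_that("matcher equals the brute-force n-gram oracle on random documents", {
  lex <- test_lexicon()
  tab <- oracle_variant_table()
  vocab <- c("paciente", "diabetes", "mellitus", "diabetes mellitus",
             "tratamiento", "antibiótico", "fiebre", "con", "sin", "el",
             "tratamiento antibiótico", "función renal", "soja", "IV",
             "madre", "y", "de", "grave", "corticoesteroides")
  set.seed(99)
  for (rep in 1:40) {
    words <- sample(vocab, sample(3:10, 1), replace = TRUE)
    doc <- mk_doc(paste(words, collapse = " "))
    got <- match_entities(doc, lex)
    want <- oracle_match(doc, tab)
    expect_identical(entity_key(got), sort(paste(want$start, want$end, want$label)))
  }
})

test_that("entities never cross sentence boundaries", {
  lex <- test_lexicon()
  doc <- mk_doc("Tratamiento frecuente. Antibiótico oral.")
  ents <- match_entities(doc, lex)
  for (i in seq_len(nrow(ents))) {
    inside <- any(doc$sentences$start <= ents$start[i] &
                    doc$sentences$end >= ents$end[i])
    expect_true(inside)
  }
})

test_that("normalization filters codes to the requested scheme", {
  lex <- test_lexicon()
  doc <- mk_doc("diabetes mellitus")
  e <- match_entities(doc, lex)[1, ]
  umls <- normalize_entity(e, lex, "UMLS")
  expect_identical(umls$codes, "UMLS:C0011849")
  sct <- normalize_entity(e, lex, "SNOMEDCT")
  expect_identical(sct$codes, "SNOMEDCT:73211009")
  unknown <- make_entities("DISO", 0, 5, "xyzzy")
  expect_identical(normalize_entity(unknown, lex, "UMLS")$codes, "")
  # entry lacking SNOMED codes yields empty codes under that scheme
  soja <- make_entities("Food_or_Drink", 0, 4, "soja")
  expect_identical(normalize_entity(soja, lex, "SNOMEDCT")$codes, "")
})
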