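test_that("cue detection: cues, pseudo suppression, speculation list", {
  cues <- detect_cues(mk_doc("Los pacientes no habían recibido tratamiento antibiótico."))
  expect_identical(cues$label, "Neg_cue")
  expect_identical(cues$surface, "no")

  expect_identical(nrow(detect_cues(mk_doc("No solo mejoró el estado general."))), 0L)

  spec <- detect_cues(mk_doc("El cuadro podría empeorar."))
  expect_identical(spec$label, "Spec_cue")
  expect_identical(spec$surface, "podría")
})

test_that("scopes run to window, terminator or sentence edge", {
  doc <- mk_doc("Paciente sin fiebre pero con cefalea intensa.")
  cues <- detect_cues(doc)
  sc <- compute_scope(cues[1, ], doc)
  # terminator "pero" closes the scope right after "fiebre"
  expect_identical(substr(doc$text, sc$start + 1, sc$end), " fiebre")

  doc2 <- mk_doc("Se descartó al final no")
  cues2 <- detect_cues(doc2)
  last_cue <- cues2[which.max(cues2$start), , drop = FALSE]
  expect_null(compute_scope(last_cue, doc2))  # cue is the final token

  doc3 <- mk_doc("no a b c d e f g h")
  sc3 <- compute_scope(detect_cues(doc3)[1, ], doc3, max_window = 6L)
  toks <- doc3$tokens
  expect_identical(sc3$end, toks$end[7])  # six tokens after the cue
})

test_that("concept-level assignment matches the worked negation sentence", {
  doc <- annotate_fixture("Los pacientes no habían recibido tratamiento antibiótico.")
  ents <- doc$entities
  cue <- ents[ents$layer == "cues", ]
  expect_identical(cue$label, "Neg_cue")
  expect_identical(cue$surface, "no")
  m <- merge(doc$attributes, ents, by.x = "target", by.y = "id")
  negated <- m[m$type == "Negated", ]
  expect_identical(negated$surface, "tratamiento antibiótico")
  # the patients themselves are not negated
  expect_false(any(m$type == "Negated" & m$surface == "pacientes"))
})

test_that("entities outside scopes get nothing; nearest cue wins", {
  doc <- mk_doc("Se evaluó la fiebre ayer.")
  ents <- match_entities(doc, test_lexicon())
  expect_identical(nrow(assign_negspec(ents, list())), 0L)

  # negation cue nearer than speculation cue: Negated wins
  doc2 <- mk_doc("posible caso y luego sin fiebre")
  cues2 <- detect_cues(doc2)
  scopes2 <- clinspan:::compute_scopes(doc2, cues2)
  ents2 <- match_entities(doc2, test_lexicon())
  at <- assign_negspec(ents2, scopes2)
  expect_identical(at$type, "Negated")
})

test_that("removing all triggers yields no negation/speculation output", {
  empty <- data.frame(pattern = character(), polarity = character(),
                      direction = character(), kind = character(),
                      stringsAsFactors = FALSE)
  doc <- mk_doc("Paciente sin fiebre ni cefalea posible.")
  expect_identical(nrow(detect_cues(doc, empty)), 0L)
})

test_that("scope assignment equals the containment/precedence oracle", {
  lex <- test_lexicon()
  cue_words <- c("no", "sin", "posible", "podría")
  fillers <- c("luego", "control", "ayer", "estable", "pero", "leve")
  concepts <- c("fiebre", "cefalea", "dolor", "paciente", "radioterapia")
  set.seed(4242)
  for (rep in 1:60) {
    words <- sample(c(sample(cue_words, sample(1:2, 1)),
                      sample(concepts, sample(1:3, 1), replace = TRUE),
                      sample(fillers, sample(0:4, 1), replace = TRUE)))
    doc <- mk_doc(paste(words, collapse = " "))
    cues <- detect_cues(doc)
    scopes <- clinspan:::compute_scopes(doc, cues)
    ents <- match_entities(doc, lex)
    got <- assign_negspec(ents, scopes)
    got_key <- sort(paste(got$target, got$type))
    expect_identical(got_key, oracle_assign(ents, scopes))
  }
})
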