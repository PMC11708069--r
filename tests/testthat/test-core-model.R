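test_that("text normalization substitutes listed characters one-for-one", {
  expect_identical(normalize_text("a b"), "a b")
  expect_identical(normalize_text(""), "")
  expect_identical(normalize_text("texto normal"), "texto normal")
  expect_identical(normalize_text("dijo “hola” – ayer"),
                   'dijo "hola" - ayer')
  expect_error(normalize_text("x", c("ab" = "c")), "single characters")
})

test_that("normalization is length-preserving and idempotent", {
  set.seed(11)
  pool <- c(letters, " ", " ", "’", "“", "–", "­",
            "á", "ñ", ".", "3")
  for (i in 1:50) {
    s <- paste(sample(pool, sample(0:40, 1), replace = TRUE), collapse = "")
    n1 <- normalize_text(s)
    expect_identical(nchar(n1), nchar(s))
    expect_identical(normalize_text(n1), n1)
  }
})

test_that("segmentation yields offset-faithful sentences and tokens", {
  doc <- mk_doc("Ensayo clínico. Fase II.")
  expect_equal(nrow(doc$sentences), 2L)
  doc1 <- mk_doc("hola")
  expect_equal(nrow(doc1$sentences), 1L)
  expect_equal(nrow(doc1$tokens), 1L)
  expect_equal(nrow(mk_doc("")$sentences), 0L)
  # offsets round-trip: surface equals text slice for every token
  for (i in seq_len(nrow(doc$tokens))) {
    expect_identical(substr(doc$text, doc$tokens$start[i] + 1, doc$tokens$end[i]),
                     doc$tokens$surface[i])
  }
  # provider returning bad offsets is an integration error
  bad_provider <- function(text) {
    list(sentences = data.frame(start = 0L, end = nchar(text)),
         tokens = data.frame(sentence = 1L, start = 0L,
                             end = nchar(text) + 5L, surface = text,
                             lemma = text, pos = "WORD"))
  }
  expect_error(segment(clin_document("hola"), bad_provider), "out of bounds")
})

test_that("the validator reports broken invariants and nothing else", {
  doc <- mk_doc("paciente con diabetes")
  expect_identical(nrow(validate_document(doc)), 0L)
  doc$entities <- make_entities("DISO", 13, 99, "diabetes")
  v <- validate_document(doc)
  expect_true(any(grepl("out of bounds", v$rule)))
  doc2 <- mk_doc("paciente con diabetes")
  doc2$entities <- make_entities("DISO", 13, 21, "diabetes")
  doc2$attributes <- make_attributes("Negated", "E99")
  v2 <- validate_document(doc2)
  expect_identical(v2$rule, "attribute targets missing entity")
})

test_that("gold corpus documents always validate cleanly", {
  docs <- gen_gold_corpus(seed = 21, n_docs = 8)
  for (d in docs) {
    expect_identical(nrow(validate_document(d)), 0L)
    for (i in seq_len(nrow(d$entities))) {
      expect_identical(substr(d$text, d$entities$start[i] + 1, d$entities$end[i]),
                       d$entities$surface[i])
    }
  }
})
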