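test_that("BIO decoding builds spans and repairs invalid transitions", {
  doc <- mk_doc("diabetes mellitus hoy")
  ents <- bio_to_spans(doc$tokens, c("B-DISO", "I-DISO", "O"), doc$text)
  expect_identical(ents$surface, "diabetes mellitus")
  expect_identical(ents$label, "DISO")

  rep_ents <- bio_to_spans(doc$tokens, c("O", "I-PROC", "O"), doc$text)
  expect_identical(rep_ents$label, "PROC")
  expect_identical(rep_ents$surface, "mellitus")

  expect_identical(nrow(bio_to_spans(doc$tokens, rep("O", 3), doc$text)), 0L)
  expect_error(bio_to_spans(doc$tokens, c("O", "O"), doc$text), "labels")

  # I- after a different class starts a new entity
  mix <- bio_to_spans(doc$tokens, c("B-DISO", "I-PROC", "O"), doc$text)
  expect_identical(mix$label, c("DISO", "PROC"))
})

test_that("the mock adapter is a faithful deterministic backend", {
  ad <- make_mock_adapter(list("diabetes" = "B-DISO",
                               "diabetes mellitus" = c("B-DISO", "I-DISO")))
  out <- ad(list(c("con", "diabetes", "mellitus", "hoy")))
  expect_identical(out[[1]]$labels, c("O", "B-DISO", "I-DISO", "O"))
  expect_identical(out[[1]]$scores, rep(1, 4))
  empty <- make_mock_adapter(list())(list(c("a", "b")))
  expect_identical(empty[[1]]$labels, c("O", "O"))
  expect_error(make_mock_adapter(list(x = "B")), "invalid BIO")
})

test_that("hybrid merge enriches codes, prefers the model, keeps ACTI", {
  text <- "diabetes y ejercicio físico"
  doc <- mk_doc(text)
  dict <- match_entities(doc, test_lexicon())
  model <- make_entities("DISO", 0, 8, "diabetes", source = "model", score = 0.9)
  merged <- merge_hybrid(model, dict)
  d <- merged[merged$label == "DISO", ]
  expect_identical(d$source, "model")
  expect_match(d$codes, "UMLS:C0011847")  # dictionary codes carried over
  expect_true("ACTI" %in% merged$label)   # dictionary-only group retained

  # overlap conflict: model span kept under model_first
  model2 <- make_entities("PROC", 0, 10, "diabetes y", source = "model")
  merged2 <- merge_hybrid(model2, dict)
  expect_identical(merged2$label[merged2$start == 0], "PROC")

  # non-overlap within the layer
  for (m in list(merged, merged2)) {
    m <- m[order(m$start), ]
    if (nrow(m) > 1) expect_true(all(m$start[-1] >= m$end[-nrow(m)]))
  }
})

test_that("bio_to_spans inverts to_bio on token-aligned entities", {
  docs <- gen_gold_corpus(seed = 5, n_docs = 4)
  for (doc in docs) {
    rows <- to_bio(doc, "umls")
    back <- bio_to_spans(doc$tokens, rows$label, doc$text)
    gold <- doc$entities[doc$entities$layer == "umls", ]
    expect_identical(entity_key(back), entity_key(gold))
  }
})

test_that("pipeline output with the mock adapter is identical across runs", {
  ad <- make_mock_adapter(list("fiebre" = "B-DISO", "paciente" = "B-LIVB"))
  cfg <- default_config(backend = "hybrid")
  text <- "El paciente presenta fiebre y ejercicio físico."
  a <- annotate(text, cfg, lexicon = test_lexicon(), adapter = ad)
  b <- annotate(text, cfg, lexicon = test_lexicon(), adapter = ad)
  expect_identical(doc_to_json(a), doc_to_json(b))
  expect_identical(a$entities, b$entities)
})
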