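test_that("BIO encoding: one label per token, B/I runs, adjacency", {
  doc <- mk_doc("fiebre cefalea ayer")
  doc$entities <- make_entities(c("DISO", "DISO"), c(0, 7), c(6, 14),
                                c("fiebre", "cefalea"))
  rows <- to_bio(doc, "umls")
  expect_identical(rows$label, c("B-DISO", "B-DISO", "O"))
  expect_identical(nrow(rows), nrow(doc$tokens))

  none <- mk_doc("sin hallazgos")
  expect_true(all(to_bio(none, "umls")$label == "O"))

  multi <- mk_doc("diabetes mellitus grave")
  multi$entities <- make_entities("DISO", 0, 17, "diabetes mellitus")
  expect_identical(to_bio(multi, "umls")$label, c("B-DISO", "I-DISO", "O"))
})

test_that("from_bio inverts to_bio and rejects unknown labels", {
  doc <- mk_doc("diabetes mellitus y fiebre")
  doc$entities <- make_entities(c("DISO", "DISO"), c(0, 20), c(17, 26),
                                c("diabetes mellitus", "fiebre"))
  rows <- to_bio(doc, "umls")
  back <- from_bio(rows, doc)
  expect_identical(entity_key(back), entity_key(doc$entities))

  bad <- rows
  bad$label[1] <- "Z-DISO"
  expect_error(from_bio(bad, doc), "unknown label")
  empty <- rows[0, ]
  expect_identical(nrow(from_bio(empty, mk_doc(""))), 0L)
})

test_that("BIO files round-trip through the CoNLL dialect", {
  doc <- mk_doc("El paciente con fiebre. Control semanal.")
  doc$entities <- make_entities(c("LIVB", "DISO"), c(3, 16), c(11, 22),
                                c("paciente", "fiebre"))
  rows <- to_bio(doc, "umls")
  path <- tempfile(fileext = ".bio")
  write_bio(rows, path)
  back <- read_bio(path)
  expect_identical(back$token, rows$token)
  expect_identical(back$label, rows$label)
  expect_identical(back$sentence, rows$sentence)
})

test_that("BRAT lines follow the standoff grammar bit-exactly", {
  doc <- mk_doc("paciente con diabetes")
  doc$entities <- make_entities("DISO", 13, 21, "diabetes",
                                codes = "UMLS:C0011847")
  doc$attributes <- make_attributes("Negated", doc$entities$id[1])
  stem <- tempfile()
  write_brat(doc, stem)
  ann <- readLines(paste0(stem, ".ann"), encoding = "UTF-8")
  expect_identical(ann[1], "T1\tDISO 13 21\tdiabetes")
  expect_identical(ann[2], "A1\tNegated T1")
  expect_identical(ann[3], "N1\tReference T1 UMLS:C0011847\tdiabetes")

  # integrity check: span must match the text slice
  writeLines("T1\tDISO 0 8\tdiabetes", paste0(stem, ".ann"))
  expect_error(read_brat(paste0(stem, ".txt")), "integrity")
})

test_that("BRAT and JSON round-trips are lossless modulo ids", {
  docs <- gen_gold_corpus(seed = 13, n_docs = 6)
  for (doc in docs) {
    stem <- tempfile()
    write_brat(doc, stem)
    back <- read_brat(paste0(stem, ".txt"))
    expect_identical(back$text, doc$text)
    expect_identical(entity_key(back$entities), entity_key(doc$entities))
    expect_identical(sort(back$entities$codes), sort(doc$entities$codes))
    expect_identical(attr_key(back), attr_key(doc))

    jdoc <- doc_from_json(doc_to_json(doc))
    expect_identical(jdoc$text, doc$text)
    expect_identical(entity_key(jdoc$entities), entity_key(doc$entities))
    expect_identical(sort(jdoc$entities$codes), sort(doc$entities$codes))
    expect_identical(attr_key(jdoc), attr_key(doc))
  }
  # empty document serializes to empty arrays
  js <- doc_to_json(mk_doc(""))
  parsed <- jsonlite::fromJSON(js)
  expect_length(parsed$entities, 0L)
})
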