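test_that("the toy lexicon file is deterministic and complete", {
  p1 <- gen_toy_lexicon(seed = 1, path = tempfile())
  p2 <- gen_toy_lexicon(seed = 1, path = tempfile())
  expect_identical(readLines(p1), readLines(p2))
  lines <- readLines(p1, encoding = "UTF-8")
  expect_true(any(grepl("^diabetes mellitus\t.*C0011849", lines)))
  expect_true(any(grepl("\tACTI\t", lines)))
  expect_true(any(grepl("^IV\t.*\t1$", lines)))  # abbreviated Route synonym
  # at least one entry for each dictionary-relevant group
  lex <- load_lexicon(p1)
  groups <- unique(unlist(lapply(lex$entries, `[[`, "groups")))
  for (g in c("ANAT", "CHEM", "DISO", "PROC", "DEVI", "GENE", "PHYS",
              "LIVB", "ACTI", "CONC", "Food_or_Drink",
              "Observation_or_Finding", "Route")) {
    expect_true(g %in% groups, label = paste("group", g, "present"))
  }
})

test_that("the gold corpus is deterministic and covers every layer", {
  a <- gen_gold_corpus(seed = 6, n_docs = 5)
  b <- gen_gold_corpus(seed = 6, n_docs = 5)
  expect_identical(lapply(a, `[[`, "text"), lapply(b, `[[`, "text"))
  expect_identical(lapply(a, `[[`, "entities"), lapply(b, `[[`, "entities"))
  expect_identical(gen_gold_corpus(seed = 6, n_docs = 0), list())
  for (doc in a) {
    for (lay in c("umls", "temporal", "medication", "misc", "cues")) {
      expect_gte(sum(doc$entities$layer == lay), 1L)
    }
  }
})

test_that("synonym augmentation replaces by shared CUI and keeps offsets valid", {
  lex <- test_lexicon()
  doc <- annotate("Se recomienda metotrexato intravenoso.", lexicon = lex)
  # pick a seed-stable augmentation; the Route full form has the IV synonyms
  aug <- augment_by_synonym(doc, lex, seed = 1)
  expect_identical(nrow(aug$entities), nrow(doc$entities))
  expect_identical(aug$entities$label, doc$entities$label)
  route_new <- aug$entities$surface[aug$entities$label == "Route"]
  expect_true(route_new %in% c("IV", "intravenosa"))
  expect_identical(nrow(validate_document(aug)), 0L)

  # entities without a synonym are left unchanged
  doc2 <- annotate("Control con carboplatino.", lexicon = lex)
  aug2 <- augment_by_synonym(doc2, lex, seed = 1)
  expect_identical(aug2$text, doc2$text)
  expect_identical(aug2$entities$surface, doc2$entities$surface)
})

test_that("augmented gold documents preserve entity counts and labels", {
  docs <- gen_gold_corpus(seed = 9, n_docs = 3)
  for (doc in docs) {
    aug <- augment_by_synonym(doc, test_lexicon(), seed = 2)
    expect_identical(nrow(aug$entities), nrow(doc$entities))
    expect_identical(sort(aug$entities$label), sort(doc$entities$label))
    expect_identical(nrow(validate_document(aug)), 0L)
  }
})

test_that("gold corpus BRAT export reads back losslessly", {
  outd <- tempfile()
  stems <- write_gold_corpus(outd, seed = 3, n_docs = 2)
  expect_length(list.files(outd, pattern = "\\.ann$"), 2L)
  doc <- read_brat(paste0(stems[1], ".txt"))
  orig <- gen_gold_corpus(seed = 3, n_docs = 2)[[1]]
  expect_identical(entity_key(doc$entities), entity_key(orig$entities))
})
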