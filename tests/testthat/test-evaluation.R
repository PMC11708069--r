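test_that("strict comparison counts exact span+label matches", {
  g <- make_entities(c("DISO", "CHEM"), c(0, 10), c(5, 15), c("aaaaa", "bbbbb"))
  same <- compare_strict(g, g)
  expect_identical(sum(same$fp) + sum(same$fn), 0L)
  shifted <- make_entities("DISO", 1, 6, "aaaaa")
  cc <- compare_strict(g[1, ], shifted)
  expect_identical(c(sum(cc$tp), sum(cc$fp), sum(cc$fn)), c(0L, 1L, 1L))
})

test_that("strict scorer equals the exhaustive set-intersection oracle", {
  set.seed(314)
  for (rep in 1:60) {
    g <- random_entity_set(sample(0:8, 1))
    p <- random_entity_set(sample(0:8, 1))
    cc <- compare_strict(g, p)
    want <- oracle_strict(g, p)
    expect_identical(c(sum(cc$tp), sum(cc$fp), sum(cc$fn)),
                     c(want[["tp"]], want[["fp"]], want[["fn"]]))
  }
})

test_that("relaxed comparison uses one-to-one overlap matching", {
  # "gastric bleeding" vs "upper gastric bleeding": overlap + same label
  g <- make_entities("DISO", 0, 22, "upper gastric bleeding")
  p <- make_entities("DISO", 6, 22, "gastric bleeding")
  cc <- compare_relaxed(g, p)
  expect_identical(sum(cc$tp), 1L)
  expect_identical(sum(cc$fp) + sum(cc$fn), 0L)

  # overlap but different label is FP + FN
  p2 <- make_entities("PROC", 6, 22, "gastric bleeding")
  cc2 <- compare_relaxed(g, p2)
  expect_identical(sum(cc2$tp), 0L)
  expect_identical(c(sum(cc2$fp), sum(cc2$fn)), c(1L, 1L))

  # two predictions over one gold: one TP, one FP
  p3 <- make_entities(c("DISO", "DISO"), c(0, 10), c(8, 22),
                      c("upper ga", "ric bleeding"))
  cc3 <- compare_relaxed(g, p3)
  expect_identical(c(sum(cc3$tp), sum(cc3$fp), sum(cc3$fn)), c(1L, 1L, 0L))
})

test_that("relaxed matching never exceeds min(|gold|, |pred|) true positives", {
  set.seed(271)
  for (rep in 1:40) {
    g <- random_entity_set(sample(0:8, 1))
    p <- random_entity_set(sample(0:8, 1))
    cc <- compare_relaxed(g, p)
    expect_lte(sum(cc$tp), min(nrow(g), nrow(p)))
    expect_identical(sum(cc$tp) + sum(cc$fn), nrow(g))
    expect_identical(sum(cc$tp) + sum(cc$fp), nrow(p))
  }
})

test_that("precision/recall/F1 closed forms and conventions hold", {
  m <- prf(list(tp = 8, fp = 2, fn = 2))
  expect_equal(unlist(m), c(P = 0.8, R = 0.8, F1 = 0.8))
  m2 <- prf(list(tp = 3, fp = 1, fn = 2))
  expect_equal(m2$P, 0.75)
  expect_equal(m2$R, 0.6)
  expect_equal(m2$F1, 2 * 0.75 * 0.6 / 1.35, tolerance = 1e-12)
  expect_equal(unlist(prf(list(tp = 0, fp = 0, fn = 0))),
               c(P = 0, R = 0, F1 = 0))
  # F1 is the harmonic mean, hence <= max(P, R)
  set.seed(5)
  for (rep in 1:20) {
    cnt <- list(tp = sample(0:9, 1), fp = sample(0:9, 1), fn = sample(0:9, 1))
    mm <- prf(cnt)
    expect_lte(mm$F1, max(mm$P, mm$R) + 1e-12)
  }
})

test_that("micro-average sums counts across labels", {
  counts <- data.frame(label = c("A", "B"), tp = c(1L, 1L),
                       fp = c(1L, 0L), fn = c(0L, 1L))
  m <- micro_average(counts)
  expect_equal(m$P, 2 / 3)
  expect_equal(m$R, 2 / 3)
  expect_equal(m$F1, 2 / 3)
  expect_equal(unlist(micro_average(counts[0, ])), c(P = 0, R = 0, F1 = 0))
})

test_that("IAA F-measure is symmetric under annotator swap", {
  a <- make_entities(c("DISO", "CHEM"), c(0, 10), c(5, 15), c("x", "y"))
  expect_equal(iaa_fmeasure(a, a)$F1, 1)
  b <- make_entities("PROC", 20, 25, "z")
  expect_equal(iaa_fmeasure(a, b)$F1, 0)
  set.seed(8)
  for (rep in 1:20) {
    s1 <- random_entity_set(sample(1:6, 1))
    s2 <- random_entity_set(sample(1:6, 1))
    expect_equal(iaa_fmeasure(s1, s2)$F1, iaa_fmeasure(s2, s1)$F1)
  }
})

test_that("corpus statistics report totals and floored two-decimal means", {
  doc <- mk_doc("paciente con fiebre")
  doc$entities <- make_entities(c("LIVB", "DISO", "DISO"), c(0, 13, 13),
                                c(8, 19, 19), c("paciente", "fiebre", "fiebre"))
  st <- corpus_stats(list(doc))
  expect_identical(st$total_entities, 3L)
  expect_equal(st$mean_entities, 3.00)
  expect_warning(st0 <- corpus_stats(list()), "empty corpus")
  expect_equal(st0$mean_entities, 0)
})
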