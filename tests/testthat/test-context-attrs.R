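attrs_for <- function(text) {
  doc <- annotate_fixture(text)
  merge(doc$attributes, doc$entities, by.x = "target", by.y = "id")
}

test_that("event temporality follows triggers and the future heuristic", {
  m <- attrs_for("El paciente refiere antecedentes de diabetes mellitus.")
  expect_identical(m$surface[m$type == "History_of"], "diabetes mellitus")

  m2 <- attrs_for("Se administrará quimioterapia con carboplatino.")
  expect_identical(m2$surface[m2$type == "Future"], "quimioterapia")

  m3 <- attrs_for("Se evaluó la quimioterapia con carboplatino.")
  expect_false("Future" %in% m3$type)

  m4 <- attrs_for("Antecedentes familiares de hipertensión arterial.")
  expect_identical(m4$type[m4$surface == "hipertensión arterial"],
                   "Family_History_of")

  m5 <- attrs_for("En caso de fiebre, avisar.")
  expect_identical(m5$surface[m5$type == "Hypothetical"], "fiebre")
})

test_that("experiencer is exactly one of Patient/Family_member/Other", {
  m <- attrs_for("La madre del paciente presenta hipertensión arterial.")
  expect_identical(m$type[m$surface == "madre"], "Family_member")
  expect_identical(m$type[m$surface == "paciente"], "Patient")
  m2 <- attrs_for("El investigador revisó los datos.")
  expect_identical(m2$type[m2$surface == "investigador"], "Other")
  # unlisted LIVB terms stay bare
  m3 <- attrs_for("Un virus causó fiebre.")
  expect_false(any(m3$surface == "virus" &
                     m3$type %in% c("Patient", "Family_member", "Other")))
})

test_that("contraindication marks CHEM/PROC in the trigger window", {
  m <- attrs_for("Pacientes con contraindicación a corticoesteroides.")
  expect_identical(m$surface[m$type == "Contraindicated"], "corticoesteroides")

  m2 <- attrs_for("Presenta contraindicación para radioterapia.")
  expect_identical(m2$surface[m2$type == "Contraindicated"], "radioterapia")

  m3 <- attrs_for("Paciente con fiebre y carboplatino pautado.")
  expect_false("Contraindicated" %in% m3$type)

  # a negation immediately before the trigger suppresses the attribute
  m4 <- attrs_for("Sujetos sin contraindicación a corticoesteroides.")
  expect_false("Contraindicated" %in% m4$type)
})

test_that("the Age attribute marks age-denoting living beings only", {
  m <- attrs_for("Los adultos y los niños acudieron con el paciente.")
  expect_setequal(m$surface[m$type == "Age"], c("adultos", "niños"))
  expect_false(any(m$surface == "paciente" & m$type == "Age"))
})

test_that("at most one temporality and one experiencer attribute per entity", {
  m <- attrs_for(paste(
    "Antecedentes de diabetes mellitus y antecedentes familiares de",
    "diabetes mellitus en la madre del paciente."))
  tab <- table(m$target, m$type)
  per_entity <- rowSums(tab[, colnames(tab) %in%
    c("History_of", "Family_History_of", "Future", "Hypothetical"),
    drop = FALSE])
  expect_true(all(per_entity <= 1))
})
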