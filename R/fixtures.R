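# Synthetic fixtures: a toy Spanish medical lexicon, a gold-annotated
# document generator built from a template grammar (each template carries
# its exact entity and attribute annotations for every layer), and the
# synonym-replacement augmentation. Everything is generated in code, so
# every module is testable without downloads; the generator emulates the
# annotation scheme (entity layers + attributes), not the distribution of
# any real corpus.

toy_lexicon_rows <- function() {
  c("lemma\tvariants\tgroups\tcuis\tsnomed\tis_abbrev",
    "paciente\tpacientes\tLIVB\tC0030705\t116154003\t0",
    "diabetes\t\tDISO\tC0011847\t73211009\t0",
    "diabetes mellitus\t\tDISO\tC0011849\t73211009\t0",
    "tratamiento\ttratamientos\tPROC\tC0087111\t276239002\t0",
    "tratamiento antibiótico\t\tPROC\tC0338237\t281789004\t0",
    "hipertensión arterial\t\tDISO\tC0020538\t38341003\t0",
    "neoplasia pulmonar\t\tDISO\tC0024121\t363358000\t0",
    "fiebre\t\tDISO\tC0015967\t386661006\t0",
    "cefalea\tcefaleas\tDISO\tC0018681\t25064002\t0",
    "dolor\tdolores\tDISO\tC0030193\t22253000\t0",
    "fractura\tfracturas\tDISO\tC0016658\t125605004\t0",
    "corticoesteroides\tcorticoesteroide|corticosteroides\tCHEM\tC0001617\t419933005\t0",
    "carboplatino\t\tCHEM\tC0079083\t386905002\t0",
    "paracetamol\t\tCHEM\tC0000970\t387517004\t0",
    "metotrexato\t\tCHEM\tC0025677\t387381009\t0",
    "bilirrubina\t\tCHEM\tC0005437\t79706000\t0",
    "quimioterapia\t\tPROC\tC0013216\t367336001\t0",
    "radioterapia\t\tPROC\tC0034619\t108290001\t0",
    "brazo\tbrazos\tANAT\tC0003798\t40983000\t0",
    "tobillo\ttobillos\tANAT\tC0003086\t344001\t0",
    "hígado\t\tANAT\tC0023884\t10200004\t0",
    "función renal\t\tPHYS\tC0232804\t11953005\t0",
    "respiración\t\tPHYS\tC0035203\t78064003\t0",
    "sonda\tsondas\tDEVI\tC0183115\t79068005\t0",
    "marcapasos\t\tDEVI\tC0030163\t14106009\t0",
    "BRAF\t\tGENE\tC0812241\t\t1",
    "madre\tmadres\tLIVB\tC0026591\t72705000\t0",
    "investigador\tinvestigadores\tLIVB\tC0035173\t\t0",
    "adulto\tadultos|adulta|adultas\tLIVB\tC0001675\t133936004\t0",
    "niño\tniños|niña|niñas\tLIVB\tC0008059\t67822003\t0",
    "virus\t\tLIVB\tC0042776\t49872002\t0",
    "ejercicio físico\t\tACTI\tC0015259\t256235009\t0",
    "soja\t\tFood_or_Drink\tC0037733\t\t0",
    "recaída\trecaídas|recaida\tObservation_or_Finding\tC0035020\t58184002\t0",
    "calidad de vida\t\tCONC\tC0034380\t\t0",
    "intravenoso\tintravenosa\tRoute\tC1522726\t47625008\t0",
    "IV\t\tRoute\tC1522726\t47625008\t1")
}

#' Generate the toy lexicon file
#'
#' Writes a small MedLexSp-style TSV covering at least one entry per
#' semantic group, a multiword DISO ("diabetes mellitus"), a Route
#' synonym pair sharing a CUI (intravenoso / abbreviation IV) and an ACTI
#' entry. Deterministic: a given seed always yields the identical file.
#'
#' @param seed integer (kept for interface symmetry; the content is
#'   fixed).
#' @param path output file (default: a tempfile).
#' @return The path, invisibly.
#' @export
gen_toy_lexicon <- function(seed = 1L, path = tempfile(fileext = ".tsv")) {
  writeLines(toy_lexicon_rows(), path, useBytes = FALSE)
  invisible(path)
}

#' Load the toy lexicon
#' @return a `clin_lexicon` built from [gen_toy_lexicon()] output.
#' @export
toy_lexicon <- function() {
  if (is.null(.res_cache$toy_lexicon)) {
    path <- gen_toy_lexicon()
    .res_cache$toy_lexicon <- load_lexicon(path)
    unlink(path)
  }
  .res_cache$toy_lexicon
}

# Template grammar. Markup: {surface|Label} or {surface|Label|Attr1,Attr2}.
# Every template is written so that the rule pipeline reproduces its gold
# annotation exactly; templates for the in-corpus worked sentences are
# fixed fixtures.
gold_templates <- function() {
  list(
    cues = c(
      "Los {pacientes|LIVB|Patient} {no|Neg_cue} habían recibido {tratamiento antibiótico|PROC|Negated}.",
      "{Sospecha de|Spec_cue} {neoplasia pulmonar|DISO|Speculated}.",
      "{Sin|Neg_cue} {fiebre|DISO|Negated} pero con {cefalea|DISO} {persistente|Quantifier_or_Qualifier}."
    ),
    experiencer = c(
      "{Pacientes|LIVB|Patient} con contraindicación a {corticoesteroides|CHEM|Contraindicated}.",
      "La {madre|LIVB|Family_member} del {paciente|LIVB|Patient} presenta {hipertensión arterial|DISO}.",
      "El {investigador|LIVB|Other} evaluó el {tratamiento|PROC}."
    ),
    temporality = c(
      "El {paciente|LIVB|Patient} refiere antecedentes de {diabetes mellitus|DISO|History_of}.",
      "Se administrará {quimioterapia|PROC|Future} con {carboplatino|CHEM}.",
      "En caso de {fiebre|DISO|Hypothetical}, administrar {paracetamol|CHEM}."
    ),
    temporal = c(
      "El {tratamiento|PROC} se mantuvo durante {dos horas|Duration}.",
      "Se administra {semanalmente|Frequency} por {vía oral|Route}.",
      "Ensayo iniciado en {2022|Date} en mayores de {18 años|Age}.",
      "El {dolor|DISO} empeora por la {noche|Time}."
    ),
    medication = c(
      "Se prescribió una {píldora|Form} de {125 mg|Dose}.",
      "Administración de {metotrexato|CHEM} {IV|Route}.",
      "Dosis de {5 mg/kg|Dose} {cada 12 horas|Frequency}."
    ),
    misc = c(
      "Criterio de inclusión: {al menos 4|Quantifier_or_Qualifier} episodios y {bilirrubina|CHEM} {< 3 UNL|Result_or_Value}.",
      "Los {adultos|LIVB|Age} evitaron la {soja|Food_or_Drink} en la dieta."
    ),
    extra = c(
      "Programa de {ejercicio físico|ACTI} supervisado.",
      "No solo mejoró la {función renal|PHYS}.",
      "Se observó {recaída|Observation_or_Finding} tras la {radioterapia|PROC}."
    )
  )
}

# parse one markup template into plain text + annotation records
parse_template <- function(tpl) {
  re <- "\\{([^|{}]+)\\|([^|{}]+?)(?:\\|([^|{}]+))?\\}"
  text <- ""
  ents <- list()
  pos <- 1L
  m <- gregexpr(re, tpl, perl = TRUE)[[1]]
  if (m[1] == -1L) return(list(text = tpl, ents = list()))
  cs <- attr(m, "capture.start"); cl <- attr(m, "capture.length")
  for (k in seq_along(m)) {
    text <- paste0(text, substr(tpl, pos, m[k] - 1L))
    surface <- substr(tpl, cs[k, 1], cs[k, 1] + cl[k, 1] - 1L)
    label <- substr(tpl, cs[k, 2], cs[k, 2] + cl[k, 2] - 1L)
    attrs <- if (cl[k, 3] > 0L) {
      strsplit(substr(tpl, cs[k, 3], cs[k, 3] + cl[k, 3] - 1L), ",")[[1]]
    } else character(0)
    start <- nchar(text)
    text <- paste0(text, surface)
    ents[[length(ents) + 1L]] <- list(surface = surface, label = label,
                                      attrs = attrs, start = start,
                                      end = nchar(text))
    pos <- m[k] + attr(m, "match.length")[k]
  }
  text <- paste0(text, substr(tpl, pos, nchar(tpl)))
  list(text = text, ents = ents)
}

# lexicon codes for a gold entity surface, filtered to UMLS (the pipeline
# default normalization)
gold_codes <- function(surface, label, lexicon) {
  lexicon_groups <- c(umls_groups(), "CONC", "Food_or_Drink",
                      "Observation_or_Finding")
  if (!label %in% lexicon_groups) return("")
  toks <- strsplit(trimws(surface), "\\s+")[[1]]
  res <- lookup_ids(lexicon, toks, tolower(toks))
  if (is.null(res)) return("")
  codes <- unique(unlist(lapply(lexicon$entries[res$ids],
                                function(e) split_pipe(entry_codes(e)))))
  paste(codes[startsWith(codes, "UMLS:")], collapse = "|")
}

#' Generate a gold-annotated synthetic corpus
#'
#' Each document draws one sentence from each template pool (negation/
#' speculation, experiencer/contraindication, event temporality, temporal
#' entities, medication, miscellaneous) plus optional extras, guaranteeing
#' at least one entity in every layer (umls, temporal, medication, misc,
#' cues). Documents carry exact gold entities and attributes; the corpus
#' is deterministic for a given seed.
#'
#' @param seed integer seed.
#' @param n_docs number of documents (>= 0).
#' @return list of segmented [clin_document()] objects with gold
#'   annotations.
#' @export
gen_gold_corpus <- function(seed = 1L, n_docs = 10L) {
  stopifnot(n_docs >= 0L)
  if (n_docs == 0L) return(list())
  pools <- gold_templates()
  lex <- toy_lexicon()
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  docs <- vector("list", n_docs)
  for (d in seq_len(n_docs)) {
    tpls <- c(
      sample(pools$cues, 1L),
      sample(pools$experiencer, 1L),
      sample(pools$temporality, 1L),
      sample(pools$temporal, 1L),
      sample(pools$medication, 1L),
      sample(pools$misc, 1L))
    if (stats::runif(1) < 0.5) tpls <- c(tpls, sample(pools$extra, 1L))
    text <- ""
    ents <- list()
    for (tpl in tpls) {
      parsed <- parse_template(tpl)
      offset <- nchar(text)
      if (nzchar(text)) {
        text <- paste0(text, " ")
        offset <- offset + 1L
      }
      text <- paste0(text, parsed$text)
      for (e in parsed$ents) {
        e$start <- e$start + offset; e$end <- e$end + offset
        ents[[length(ents) + 1L]] <- e
      }
    }
    doc <- clin_document(text, doc_id = sprintf("synth%03d", d))
    doc <- segment(doc)
    if (length(ents)) {
      labels <- vapply(ents, `[[`, character(1), "label")
      starts <- vapply(ents, `[[`, numeric(1), "start")
      ends <- vapply(ents, `[[`, numeric(1), "end")
      surfs <- vapply(ents, `[[`, character(1), "surface")
      codes <- vapply(seq_along(ents), function(i) {
        gold_codes(surfs[i], labels[i], lex)
      }, character(1))
      doc$entities <- make_entities(labels, starts, ends, surfs,
                                    source = "gold", codes = codes)
      at <- list()
      for (i in seq_along(ents)) {
        for (a in ents[[i]]$attrs) {
          at[[length(at) + 1L]] <- c(type = trimws(a),
                                     target = doc$entities$id[i])
        }
      }
      if (length(at)) {
        doc$attributes <- make_attributes(
          vapply(at, `[[`, character(1), "type"),
          vapply(at, `[[`, character(1), "target"))
      }
    }
    docs[[d]] <- doc
  }
  docs
}

#' Write a gold corpus as BRAT pairs
#'
#' @param out_dir output directory.
#' @param seed,n_docs passed to [gen_gold_corpus()].
#' @return Invisibly, the document stems written.
#' @export
write_gold_corpus <- function(out_dir, seed = 1L, n_docs = 10L) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  docs <- gen_gold_corpus(seed, n_docs)
  stems <- character(0)
  for (doc in docs) {
    stem <- file.path(out_dir, doc$doc_id)
    write_brat(doc, stem)
    stems <- c(stems, stem)
  }
  invisible(stems)
}

#' Synonym-replacement augmentation
#'
#' Replaces entity surfaces by a lexicon variant sharing a UMLS CUI (e.g.
#' full form "intravenoso" by the abbreviation "IV"), recomputing all
#' downstream offsets and preserving gold labels and attributes. Entities
#' without a synonym (or partially overlapping another entity) are left
#' unchanged.
#'
#' @param doc a [clin_document()] whose entities carry codes present in
#'   the lexicon (surfaces are looked up when codes are absent).
#' @param lexicon a [load_lexicon()] result.
#' @param seed integer seed for the variant choice.
#' @return The augmented, re-segmented document.
#' @export
augment_by_synonym <- function(doc, lexicon, seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  e <- doc$entities
  if (!nrow(e)) return(doc)
  # candidate replacement per entity
  repl <- rep(NA_character_, nrow(e))
  for (i in seq_len(nrow(e))) {
    cuis <- sub("^UMLS:", "", grep("^UMLS:", split_pipe(e$codes[i]), value = TRUE))
    if (!length(cuis)) {
      toks <- strsplit(trimws(e$surface[i]), "\\s+")[[1]]
      res <- lookup_ids(lexicon, toks, tolower(toks))
      if (!is.null(res)) {
        cuis <- unique(unlist(lapply(lexicon$entries[res$ids], `[[`, "cuis")))
      }
    }
    if (!length(cuis)) next
    variants <- unique(unlist(lapply(lexicon$entries, function(en) {
      if (any(en$cuis %in% cuis)) en$variants else character(0)
    })))
    variants <- setdiff(variants, e$surface[i])
    variants <- variants[fold(variants) != fold(e$surface[i])]
    if (length(variants)) repl[i] <- sample(variants, 1L)
  }
  # apply replacements right-to-left so earlier offsets stay valid
  ord <- order(-e$start)
  text <- doc$text
  for (i in ord) {
    if (is.na(repl[i])) next
    s <- e$start[i]; en_ <- e$end[i]
    partial <- any(e$start < en_ & e$end > s &
                     !(e$start >= s & e$end <= en_) &
                     !(e$start <= s & e$end >= en_))
    if (partial) next
    delta <- nchar(repl[i]) - (en_ - s)
    text <- paste0(slice_text(text, 0L, s), repl[i],
                   slice_text(text, en_, nchar(text)))
    for (j in seq_len(nrow(e))) {
      if (j == i) next
      if (e$start[j] >= en_) {
        e$start[j] <- e$start[j] + delta; e$end[j] <- e$end[j] + delta
      } else if (e$start[j] <= s && e$end[j] >= en_) {
        e$end[j] <- e$end[j] + delta
      }
    }
    e$end[i] <- s + nchar(repl[i])
    e$surface[i] <- repl[i]
  }
  out <- clin_document(text, doc_id = doc$doc_id)
  out <- segment(out)
  for (j in seq_len(nrow(e))) {
    e$surface[j] <- slice_text(out$text, e$start[j], e$end[j])
  }
  out$entities <- e
  out$attributes <- doc$attributes
  out
}
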