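# ConText-style attributes: event temporality (History_of,
# Family_History_of, Future, Hypothetical), experiencer (Patient,
# Family_member, Other), Contraindicated, and the Age attribute on
# age-denoting living-being entities.

temporality_eligible_labels <- function() c("DISO", "PROC", "PHYS")

#' Load the packaged attribute resources
#'
#' @return list with trigger tables and term lists used by the attribute
#'   assigners.
#' @export
load_attr_resources <- function() {
  tt <- read_lines_utf8(res_path("temporality_triggers.tsv"))
  parts <- strsplit(tt, "\t", fixed = TRUE)
  temporality <- data.frame(
    pattern = vapply(parts, `[[`, character(1), 1),
    attr = vapply(parts, `[[`, character(1), 2),
    direction = vapply(parts, `[[`, character(1), 3),
    stringsAsFactors = FALSE)
  ct <- read_lines_utf8(res_path("contraindication_triggers.tsv"))
  parts <- strsplit(ct, "\t", fixed = TRUE)
  contraind <- data.frame(
    pattern = vapply(parts, `[[`, character(1), 1),
    direction = vapply(parts, `[[`, character(1), 2),
    stringsAsFactors = FALSE)
  list(
    temporality = temporality,
    contraindication = contraind,
    patient_terms = fold(read_term_list(res_path("experiencer_patient.txt"))),
    kin_terms = fold(read_term_list(res_path("experiencer_kin.txt"))),
    role_terms = fold(read_term_list(res_path("experiencer_role.txt"))),
    age_terms = fold(read_term_list(res_path("age_terms.txt")))
  )
}

# generic windowed trigger->entity assignment within sentences
trigger_assign <- function(doc, entities, rows, window = 8L,
                           eligible_labels = NULL) {
  # rows: data.frame(pattern, attr, direction)
  hits <- list()
  if (!nrow(entities)) return(hits)
  elig <- entities
  if (!is.null(eligible_labels)) {
    elig <- elig[elig$label %in% eligible_labels, , drop = FALSE]
  }
  if (!nrow(elig)) return(hits)
  for (k in seq_len(nrow(doc$sentences))) {
    s0 <- doc$sentences$start[k]; s1 <- doc$sentences$end[k]
    s_txt <- slice_text(doc$text, s0, s1)
    toks <- sentence_tokens(doc, k)
    for (r in seq_len(nrow(rows))) {
      m <- re_find(s_txt, bounded(rows$pattern[r]))
      for (j in seq_len(nrow(m))) {
        t_start <- m$start[j] + s0; t_end <- m$end[j] + s0
        if (rows$direction[r] == "pre") {
          after <- which(toks$start >= t_end)
          if (!length(after)) next
          take <- after[seq_len(min(window, length(after)))]
          w_start <- t_end; w_end <- toks$end[take[length(take)]]
        } else {
          before <- which(toks$end <= t_start)
          if (!length(before)) next
          take <- rev(before)[seq_len(min(window, length(before)))]
          w_start <- toks$start[take[length(take)]]; w_end <- t_start
        }
        inside <- which(elig$start >= w_start & elig$end <= w_end)
        for (i in inside) {
          d <- if (elig$start[i] >= t_end) elig$start[i] - t_end
               else t_start - elig$end[i]
          hits[[length(hits) + 1L]] <- list(
            target = elig$id[i], attr = rows$attr[r], dist = d,
            trig_start = t_start)
        }
      }
    }
  }
  hits
}

#' Assign event-temporality attributes
#'
#' Triggers ("antecedentes de", "en caso de", ...) within an 8-token
#' directional window in the same sentence mark DISO/PROC/PHYS entities.
#' An optional heuristic treats simple-future verb forms (-rá/-rán) as
#' Future triggers. Per entity the nearest trigger wins; at equal distance
#' precedence is Family_History_of > History_of > Hypothetical > Future.
#'
#' @param doc a segmented [clin_document()].
#' @param entities the umls-layer entity table.
#' @param resources [load_attr_resources()] output.
#' @param window token window (default 8).
#' @param future_heuristic detect -rá/-rán verb forms (default TRUE).
#' @return Attribute data.frame.
#' @export
assign_temporality <- function(doc, entities,
                               resources = load_attr_resources(),
                               window = 8L, future_heuristic = TRUE) {
  rows <- resources$temporality
  if (future_heuristic) {
    rows <- rbind(rows, data.frame(
      pattern = "[\\p{L}]{2,}rá(?:n)?", attr = "Future", direction = "pre",
      stringsAsFactors = FALSE))
  }
  hits <- trigger_assign(doc, entities, rows, window,
                         temporality_eligible_labels())
  pick_one_per_entity(hits,
                      precedence = c("Family_History_of", "History_of",
                                     "Hypothetical", "Future"))
}

# nearest trigger wins; ties broken by the precedence order given
pick_one_per_entity <- function(hits, precedence) {
  if (!length(hits)) return(empty_attributes())
  tg <- vapply(hits, `[[`, character(1), "target")
  types <- character(0); targets <- character(0)
  for (t in unique(tg)) {
    hs <- hits[tg == t]
    d <- vapply(hs, `[[`, numeric(1), "dist")
    hs <- hs[d == min(d)]
    at <- vapply(hs, `[[`, character(1), "attr")
    at <- at[order(match(at, precedence))][1]
    types <- c(types, at); targets <- c(targets, t)
  }
  make_attributes(types, targets)
}

#' Assign experiencer attributes
#'
#' Human-denoting LIVB entities whose folded surface (or head token) is in
#' one of the packaged lists receive exactly one of Patient,
#' Family_member or Other; unlisted LIVB terms are left bare.
#'
#' @inheritParams assign_temporality
#' @return Attribute data.frame.
#' @export
assign_experiencer <- function(doc, entities,
                               resources = load_attr_resources()) {
  livb <- entities[entities$label == "LIVB", , drop = FALSE]
  if (!nrow(livb)) return(empty_attributes())
  types <- character(0); targets <- character(0)
  for (i in seq_len(nrow(livb))) {
    key <- fold(livb$surface[i])
    at <- if (key %in% resources$kin_terms) "Family_member"
          else if (key %in% resources$role_terms) "Other"
          else if (key %in% resources$patient_terms) "Patient"
          else NA_character_
    if (!is.na(at)) { types <- c(types, at); targets <- c(targets, livb$id[i]) }
  }
  make_attributes(types, targets)
}

#' Assign the Contraindicated attribute
#'
#' CHEM/PROC entities within a 6-token window of a contraindication
#' trigger ("contraindicación a/para", "contraindicado/a") are marked
#' Contraindicated. A negation cue token immediately before the trigger
#' ("sin contraindicación a") suppresses the assignment.
#'
#' @inheritParams assign_temporality
#' @param window token window (default 6).
#' @return Attribute data.frame.
#' @export
assign_contraindicated <- function(doc, entities,
                                   resources = load_attr_resources(),
                                   window = 6L) {
  rows <- resources$contraindication
  rows$attr <- "Contraindicated"
  hits <- trigger_assign(doc, entities, rows, window, c("CHEM", "PROC"))
  if (!length(hits)) return(empty_attributes())
  # suppress when the token right before the trigger is a negation word
  keep <- vapply(hits, function(h) {
    prev <- doc$tokens[doc$tokens$end <= h$trig_start, , drop = FALSE]
    if (!nrow(prev)) return(TRUE)
    !fold(prev$surface[nrow(prev)]) %in% c("sin", "no", "ninguna", "ningun")
  }, logical(1))
  pick_one_per_entity(hits[keep], precedence = "Contraindicated")
}

#' Assign the Age attribute to age-denoting LIVB entities
#'
#' @param entities the umls-layer entity table.
#' @param age_term_list folded list of age-denoting LIVB terms
#'   ("adultos", "niños", ...).
#' @return Attribute data.frame.
#' @export
assign_age_attr <- function(entities,
                            age_term_list = load_attr_resources()$age_terms) {
  livb <- entities[entities$label == "LIVB", , drop = FALSE]
  if (!nrow(livb)) return(empty_attributes())
  hit <- fold(livb$surface) %in% age_term_list
  make_attributes(rep("Age", sum(hit)), livb$id[hit])
}
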