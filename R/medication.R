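# Medication information tagger: Dose (dose/concentration/strength merged
# into one class), Route (administration route) and Form (dosage form),
# driven by editable packaged term lists and a unit grammar.

#' Load the medication term lists
#'
#' Routes, dosage forms and dose units come from one-entry-per-line UTF-8
#' files. Form and route entries get plural variants expanded at load;
#' all-uppercase route entries are treated as abbreviations and matched
#' case-sensitively.
#'
#' @param routes,forms,units optional overriding file paths.
#' @return list with elements `routes`, `route_abbrevs`, `forms`, `units`.
#' @export
load_med_terms <- function(routes = res_path("routes.txt"),
                           forms = res_path("forms.txt"),
                           units = res_path("dose_units.txt")) {
  r <- read_term_list(routes)
  is_abbrev <- r == toupper(r) & nchar(r) <= 4L
  list(routes = unique(fold(expand_plurals(r[!is_abbrev]))),
       route_abbrevs = r[is_abbrev],
       forms = unique(fold(expand_plurals(read_term_list(forms)))),
       units = read_term_list(units))
}

# naive Spanish plural expansion: vowel-final +s, consonant-final +es,
# -z -> -ces ("vez" -> "veces")
expand_plurals <- function(x) {
  pl <- ifelse(grepl("[aeiouáéíóú]$", x), paste0(x, "s"),
        ifelse(grepl("z$", x), paste0(sub("z$", "", x), "ces"),
               paste0(x, "es")))
  unique(c(x, pl))
}

dose_unit_pattern <- function(units) {
  # longest-first alternation; compound denominators per kg/m2/day/hour/dose
  u <- units[order(-nchar(units))]
  core <- paste0("(?:", paste(u, collapse = "|"), ")")
  paste0(core, "(?:\\s*/\\s*(?:", paste(u, collapse = "|"),
         "|kg|m2|m²|m\\^2|día|dia|h|dosis|toma))*")
}

#' Tag Dose entities
#'
#' Matches a number (digits, decimal comma/dot or number word), optionally
#' a range (`10-20`), followed by a dose unit with optional compound
#' denominators (`mg/kg`, `mg/m²`). The span runs from the number through
#' the unit; a bare unit is never tagged.
#'
#' @param doc a segmented [clin_document()].
#' @param units character vector of unit strings.
#' @return Entity data.frame (label Dose).
#' @export
tag_dose <- function(doc, units = load_med_terms()$units) {
  if (!is_segmented(doc)) stop("document must be segmented")
  digit <- "\\d+(?:[.,]\\d+)?"
  # digits may abut the unit ("125mg"); number words need whitespace so
  # that e.g. "UNL" is not read as "un" + unit "L"
  num_part <- paste0("(?:", digit, "(?:\\s*[-–]\\s*", digit, ")?\\s*|",
                     number_word_pattern(), "\\s+)")
  pat <- bounded(paste0(num_part, dose_unit_pattern(units)))
  tag_by_pattern(doc, pat, "Dose")
}

# run a bounded case-insensitive pattern over sentences, resolve overlaps
tag_by_pattern <- function(doc, pattern, label, ignore_case = TRUE) {
  out <- list()
  for (k in seq_len(nrow(doc$sentences))) {
    s0 <- doc$sentences$start[k]
    s_txt <- slice_text(doc$text, s0, doc$sentences$end[k])
    m <- re_find(s_txt, pattern, ignore_case)
    if (!nrow(m)) next
    m$start <- m$start + s0; m$end <- m$end + s0
    m$priority <- 1L
    out[[length(out) + 1L]] <- resolve_overlaps(m)
  }
  if (!length(out)) return(empty_entities())
  res <- do.call(rbind, out)
  make_entities(rep(label, nrow(res)), res$start, res$end,
                vapply(seq_len(nrow(res)),
                       function(i) slice_text(doc$text, res$start[i], res$end[i]),
                       character(1)),
                source = "rules")
}

# match a folded term list against token n-grams of a sentence
match_term_list <- function(doc, terms, label, max_len = NULL,
                            abbrevs = character(0)) {
  if (is.null(max_len)) {
    max_len <- max(1L, lengths(strsplit(terms, "\\s+")))
  }
  term_set <- terms
  out <- list()
  for (k in seq_len(nrow(doc$sentences))) {
    toks <- sentence_tokens(doc, k)
    n <- nrow(toks)
    i <- 1L
    while (i <= n) {
      hit_len <- 0L
      for (len in seq(min(max_len, n - i + 1L), 1L)) {
        idx <- i:(i + len - 1L)
        if (paste(toks$surface[idx], collapse = " ") %in% abbrevs ||
            paste(fold(toks$surface[idx]), collapse = " ") %in% term_set) {
          hit_len <- len
          break
        }
      }
      if (hit_len == 0L) { i <- i + 1L; next }
      idx <- i:(i + hit_len - 1L)
      out[[length(out) + 1L]] <- data.frame(
        start = toks$start[idx[1]], end = toks$end[idx[hit_len]],
        sentence = k, first_tok = i, stringsAsFactors = FALSE)
      i <- i + hit_len
    }
  }
  if (!length(out)) return(empty_entities())
  res <- do.call(rbind, out)
  ents <- make_entities(rep(label, nrow(res)), res$start, res$end,
                        vapply(seq_len(nrow(res)),
                               function(i) slice_text(doc$text, res$start[i], res$end[i]),
                               character(1)),
                        source = "rules")
  attr(ents, "match_meta") <- res
  ents
}

#' Tag Route entities
#'
#' List/lemma match over the route vocabulary (case- and accent-folded),
#' with all-uppercase abbreviations (IV, SC...) matched case-sensitively.
#' A preceding "vía"/"via" token is absorbed into the span ("vía oral").
#'
#' @param doc a segmented [clin_document()].
#' @param terms result of [load_med_terms()] (or a compatible list).
#' @return Entity data.frame (label Route).
#' @export
tag_route <- function(doc, terms = load_med_terms()) {
  if (!is_segmented(doc)) stop("document must be segmented")
  ents <- match_term_list(doc, terms$routes, "Route",
                          abbrevs = terms$route_abbrevs)
  meta <- attr(ents, "match_meta")
  if (!is.null(meta) && nrow(ents)) {
    for (i in seq_len(nrow(ents))) {
      toks <- sentence_tokens(doc, meta$sentence[i])
      j <- meta$first_tok[i]
      if (j > 1L && fold(toks$surface[j - 1L]) %in% c("via")) {
        ents$start[i] <- toks$start[j - 1L]
        ents$surface[i] <- slice_text(doc$text, ents$start[i], ents$end[i])
      }
    }
  }
  attr(ents, "match_meta") <- NULL
  ents
}

#' Tag Form entities
#'
#' Folded list match over the dosage-form vocabulary, including plural
#' variants expanded at load ("comprimidos").
#'
#' @inheritParams tag_route
#' @return Entity data.frame (label Form).
#' @export
tag_form <- function(doc, terms = load_med_terms()) {
  if (!is_segmented(doc)) stop("document must be segmented")
  ents <- match_term_list(doc, terms$forms, "Form")
  attr(ents, "match_meta") <- NULL
  ents
}
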