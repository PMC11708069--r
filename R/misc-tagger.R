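# Miscellaneous clinical entities: Result_or_Value and
# Quantifier_or_Qualifier by pattern/list, and the lexicon-driven classes
# CONC, Food_or_Drink and Observation_or_Finding.

#' Tag Result_or_Value entities
#'
#' Matches a comparator (&lt;, &gt;, <=, >=, =) followed by a number and an
#' optional unit token (percent sign, an uppercase-looking unit such as
#' "UNL", or a dose unit). The span runs from the comparator through the
#' unit; a bare number is never tagged.
#'
#' @param doc a segmented [clin_document()].
#' @param units dose-unit list used to accept lab/dose units after the
#'   number.
#' @return Entity data.frame (label Result_or_Value).
#' @export
tag_result_value <- function(doc, units = load_med_terms()$units) {
  if (!is_segmented(doc)) stop("document must be segmented")
  u <- units[order(-nchar(units))]
  unit_alt <- paste0("(?:%|", paste(u, collapse = "|"),
                     "|[A-ZÁÉÍÓÚÑ][A-Za-zÁÉÍÓÚÑáéíóúñ]{0,5}(?:/[A-Za-z]{1,3})?)")
  pat <- paste0("(?:<=|>=|≤|≥|<|>|=)\\s*", number_pattern(),
                "(?:\\s*", unit_alt, ")?(?![\\p{L}\\p{N}])")
  ents <- tag_by_pattern(doc, pat, "Result_or_Value", ignore_case = FALSE)
  ents
}

#' Tag Quantifier_or_Qualifier entities
#'
#' Two sources: quantity phrases ("al menos 4", "un máximo de 2") and a
#' packaged list of qualifier adjectives (severity, laterality, extent),
#' matched case/accent-folded with plural expansion.
#'
#' @param doc a segmented [clin_document()].
#' @param qualifier_list character vector of qualifier adjectives.
#' @return Entity data.frame (label Quantifier_or_Qualifier).
#' @export
tag_quantifier <- function(doc,
                           qualifier_list = read_term_list(res_path("qualifiers.txt"))) {
  if (!is_segmented(doc)) stop("document must be segmented")
  num <- number_pattern()
  pat <- paste0("(?:al\\s+menos\\s+", num,
                "|como\\s+m[áa]ximo\\s+", num,
                "|un\\s+m[áa]ximo\\s+de\\s+", num,
                "|un\\s+m[íi]nimo\\s+de\\s+", num, ")")
  quant <- tag_by_pattern(doc, bounded(pat), "Quantifier_or_Qualifier")
  qual <- match_term_list(doc, unique(fold(expand_plurals(qualifier_list))),
                          "Quantifier_or_Qualifier")
  attr(qual, "match_meta") <- NULL
  both <- rbind(quant, qual)
  if (!nrow(both)) return(both)
  both$priority <- ifelse(seq_len(nrow(both)) <= nrow(quant), 2L, 1L)
  kept <- resolve_overlaps(both)
  kept$priority <- NULL
  kept$id <- paste0("E", seq_len(nrow(kept)))
  kept
}

#' Tag lexicon-driven miscellaneous entities
#'
#' Delegates to [match_entities()] restricted to the CONC, Food_or_Drink
#' and Observation_or_Finding groups.
#'
#' @param doc a segmented [clin_document()].
#' @param lexicon a [load_lexicon()] result.
#' @return Entity data.frame.
#' @export
tag_misc_lexicon <- function(doc, lexicon) {
  match_entities(doc, lexicon,
                 include_groups = c("CONC", "Food_or_Drink",
                                    "Observation_or_Finding"))
}
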