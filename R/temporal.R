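# Temporal entity tagger: HeidelTime-inspired rules for Spanish covering
# the TimeML-style classes Date, Duration, Frequency and Time, plus Age
# (age mentions matter for trial eligibility). Rules live in an editable
# packaged table; spans never cross sentence boundaries.

time_unit_pattern <- function() {
  paste0("(?:segundos?|minutos?|horas?|días?|dias?|semanas?|",
         "mes(?:es)?|años?|anos?)")
}

expand_macros <- function(pattern) {
  pattern <- gsub("<NUM>", number_pattern(), pattern, fixed = TRUE)
  gsub("<TUNIT>", time_unit_pattern(), pattern, fixed = TRUE)
}

#' Load temporal rules from a TSV table
#'
#' One rule per line: `pattern TAB class TAB priority`. Patterns are Perl
#' regexes matched case-insensitively inside one sentence; `<NUM>` and
#' `<TUNIT>` macros expand to a number (digits or Spanish number words)
#' and a time unit. A capture group 1 narrows the annotated span.
#'
#' @param path rule file (default: the packaged table).
#' @return data.frame of compiled rules with class `clin_temporal_rules`.
#' @export
load_temporal_rules <- function(path = res_path("temporal_rules.tsv")) {
  lines <- read_lines_utf8(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) stop("temporal rule file: bad line ", bad[1])
  klass <- vapply(parts, `[[`, character(1), 2)
  ok <- klass %in% c("Date", "Duration", "Frequency", "Time", "Age")
  if (!all(ok)) stop("temporal rule file: unknown class ", klass[!ok][1])
  rules <- data.frame(
    pattern = vapply(parts, function(p) bounded(expand_macros(p[1])), character(1)),
    klass = klass,
    priority = as.integer(vapply(parts, `[[`, character(1), 3)),
    stringsAsFactors = FALSE)
  # compile check
  for (p in rules$pattern) regexpr(p, "", perl = TRUE)
  class(rules) <- c("clin_temporal_rules", class(rules))
  rules
}

# tokens folded for trigger-word checks
age_trigger_tokens <- c("edad", "mayores", "menores", "cumplidos")

#' Tag temporal entities
#'
#' Applies the rule table sentence by sentence, collects candidate spans,
#' promotes `N años` Duration candidates to Age when an age trigger
#' ("edad", "mayores/menores de", "de edad") occurs within a 4-token
#' window, then resolves overlaps by priority, length and position.
#'
#' @param doc a segmented [clin_document()].
#' @param rules a [load_temporal_rules()] table.
#' @return Entity data.frame (labels Date, Duration, Frequency, Time, Age).
#' @export
tag_temporal <- function(doc, rules = load_temporal_rules()) {
  if (!is_segmented(doc)) stop("document must be segmented")
  out <- list()
  for (k in seq_len(nrow(doc$sentences))) {
    s0 <- doc$sentences$start[k]
    s_txt <- slice_text(doc$text, s0, doc$sentences$end[k])
    toks <- sentence_tokens(doc, k)
    cands <- list()
    for (r in seq_len(nrow(rules))) {
      m <- re_find(s_txt, rules$pattern[r])
      if (!nrow(m)) next
      m$start <- m$start + s0; m$end <- m$end + s0
      m$klass <- rules$klass[r]; m$priority <- rules$priority[r]
      cands[[length(cands) + 1L]] <- m
    }
    if (!length(cands)) next
    cands <- do.call(rbind, cands)
    # Age disambiguation: "N años" is Age only near an age trigger
    is_years <- cands$klass == "Duration" &
      grepl("años?\\s*$|anos?\\s*$",
            vapply(seq_len(nrow(cands)),
                   function(i) fold(slice_text(doc$text, cands$start[i], cands$end[i])),
                   character(1)))
    for (i in which(is_years)) {
      idx <- tokens_in_span(toks, cands$start[i], cands$end[i])
      if (!length(idx)) next
      lo <- max(1L, min(idx) - 4L); hi <- min(nrow(toks), max(idx) + 4L)
      window <- fold(toks$surface[setdiff(lo:hi, idx)])
      if (any(window %in% age_trigger_tokens)) {
        cands$klass[i] <- "Age"
        cands$priority[i] <- 40L
      }
    }
    kept <- resolve_overlaps(cands)
    if (nrow(kept)) out[[length(out) + 1L]] <- kept
  }
  if (!length(out)) return(empty_entities())
  res <- do.call(rbind, out)
  make_entities(res$klass, res$start, res$end,
                vapply(seq_len(nrow(res)),
                       function(i) slice_text(doc$text, res$start[i], res$end[i]),
                       character(1)),
                source = "rules")
}
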