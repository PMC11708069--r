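# NegEx/ConText-style negation and speculation, translated to Spanish.
# Cues are annotated as entities (Neg_cue, Spec_cue); scopes are computed
# per sentence but never annotated as spans: attributes (Negated,
# Speculated) attach to concepts fully inside a scope, following the
# concept-level annotation scheme.

#' Load a trigger table
#'
#' UTF-8 TSV with columns `pattern`, `polarity`, `direction`, `kind`
#' (cue | pseudo | termination). Patterns are Perl regexes matched
#' case-insensitively with word boundaries added.
#'
#' @param path trigger file (default: the packaged negation/speculation
#'   table).
#' @return data.frame of triggers.
#' @export
load_triggers <- function(path = res_path("negspec_triggers.tsv")) {
  lines <- read_lines_utf8(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 4L)
  if (length(bad)) stop("trigger file: bad line ", bad[1])
  tr <- data.frame(
    pattern = vapply(parts, `[[`, character(1), 1),
    polarity = vapply(parts, `[[`, character(1), 2),
    direction = vapply(parts, `[[`, character(1), 3),
    kind = vapply(parts, `[[`, character(1), 4),
    stringsAsFactors = FALSE)
  ok_kind <- tr$kind %in% c("cue", "pseudo", "termination")
  if (!all(ok_kind)) stop("trigger file: unknown kind ", tr$kind[!ok_kind][1])
  ok_pol <- tr$polarity %in% c("negation", "speculation", "-")
  if (!all(ok_pol)) stop("trigger file: unknown polarity ", tr$polarity[!ok_pol][1])
  ok_dir <- tr$direction %in% c("pre", "post", "-")
  if (!all(ok_dir)) stop("trigger file: unknown direction ", tr$direction[!ok_dir][1])
  tr
}

# all matches of the trigger rows of given kinds within one sentence
trigger_matches <- function(s_txt, s0, triggers, kinds) {
  rows <- triggers[triggers$kind %in% kinds, , drop = FALSE]
  out <- list()
  for (r in seq_len(nrow(rows))) {
    m <- re_find(s_txt, bounded(rows$pattern[r]))
    if (!nrow(m)) next
    m$start <- m$start + s0; m$end <- m$end + s0
    m$polarity <- rows$polarity[r]
    m$direction <- rows$direction[r]
    m$kind <- rows$kind[r]
    out[[length(out) + 1L]] <- m
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(),
                      polarity = character(), direction = character(),
                      kind = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Detect negation and speculation cues
#'
#' Longest trigger match wins at a position; any cue match contained in a
#' pseudo-trigger match is suppressed (e.g. "no solo" emits no cue for
#' "no").
#'
#' @param doc a segmented [clin_document()].
#' @param triggers a [load_triggers()] table.
#' @return Entity data.frame (labels Neg_cue, Spec_cue).
#' @export
detect_cues <- function(doc, triggers = load_triggers()) {
  if (!is_segmented(doc)) stop("document must be segmented")
  out <- list()
  for (k in seq_len(nrow(doc$sentences))) {
    s0 <- doc$sentences$start[k]
    s_txt <- slice_text(doc$text, s0, doc$sentences$end[k])
    m <- trigger_matches(s_txt, s0, triggers, c("cue", "pseudo"))
    if (!nrow(m)) next
    pseudo <- m[m$kind == "pseudo", , drop = FALSE]
    cues <- m[m$kind == "cue", , drop = FALSE]
    if (nrow(cues) && nrow(pseudo)) {
      suppressed <- vapply(seq_len(nrow(cues)), function(i) {
        any(cues$start[i] >= pseudo$start & cues$end[i] <= pseudo$end)
      }, logical(1))
      cues <- cues[!suppressed, , drop = FALSE]
    }
    if (!nrow(cues)) next
    cues$priority <- 1L
    kept <- resolve_overlaps(cues)  # longest wins on ties by construction
    out[[length(out) + 1L]] <- kept
  }
  if (!length(out)) return(empty_entities())
  res <- do.call(rbind, out)
  make_entities(ifelse(res$polarity == "negation", "Neg_cue", "Spec_cue"),
                res$start, res$end,
                vapply(seq_len(nrow(res)),
                       function(i) slice_text(doc$text, res$start[i], res$end[i]),
                       character(1)),
                source = "rules")
}

#' Compute the scope of one cue
#'
#' Pre-cue scopes run forward from the cue end to the earliest of sentence
#' end, the first termination trigger, or `max_window` tokens; post-cue
#' scopes mirror this backwards. Returns NULL when the scope is empty.
#'
#' @param cue one-row entity data.frame (a cue).
#' @param doc the segmented document containing the cue.
#' @param triggers trigger table (for termination terms).
#' @param max_window token window (default 6, NegEx heritage).
#' @param direction `"pre"` or `"post"`.
#' @return list(start, end, cue_start, cue_end, polarity) or NULL.
#' @export
compute_scope <- function(cue, doc, triggers = load_triggers(),
                          max_window = 6L, direction = "pre") {
  k <- which(doc$sentences$start <= cue$start & doc$sentences$end >= cue$end)
  if (!length(k)) return(NULL)
  k <- k[1]
  s0 <- doc$sentences$start[k]; s1 <- doc$sentences$end[k]
  s_txt <- slice_text(doc$text, s0, s1)
  toks <- sentence_tokens(doc, k)
  terms <- trigger_matches(s_txt, s0, triggers, "termination")
  if (direction == "pre") {
    after <- which(toks$start >= cue$end)
    if (!length(after)) return(NULL)
    take <- after[seq_len(min(max_window, length(after)))]
    end <- toks$end[take[length(take)]]
    stop_at <- terms$start[terms$start >= cue$end]
    if (length(stop_at)) end <- min(end, min(stop_at))
    # snap to the last token ending inside the scope
    ends <- toks$end[toks$end <= end & toks$end > cue$end]
    if (!length(ends)) return(NULL)
    end <- max(ends)
    start <- cue$end
    if (end <= start) return(NULL)
  } else {
    before <- which(toks$end <= cue$start)
    if (!length(before)) return(NULL)
    take <- rev(before)[seq_len(min(max_window, length(before)))]
    start <- toks$start[take[length(take)]]
    stop_at <- terms$end[terms$end <= cue$start]
    if (length(stop_at)) start <- max(start, max(stop_at))
    starts <- toks$start[toks$start >= start & toks$start < cue$start]
    if (!length(starts)) return(NULL)
    start <- min(starts)
    end <- cue$start
    if (end <= start) return(NULL)
  }
  list(start = start, end = end,
       cue_start = cue$start, cue_end = cue$end,
       polarity = if (cue$label == "Neg_cue") "negation" else "speculation")
}

# scopes for every cue entity in a document
compute_scopes <- function(doc, cues, triggers = load_triggers(),
                           max_window = 6L) {
  scopes <- list()
  for (i in seq_len(nrow(cues))) {
    cue <- cues[i, , drop = FALSE]
    # direction from the trigger table row that produced the cue: recover by
    # matching; cues from pre rows dominate the starter tables, post rows
    # are those whose pattern matches the cue surface with direction post
    dir <- "pre"
    rows <- triggers[triggers$kind == "cue", , drop = FALSE]
    for (r in seq_len(nrow(rows))) {
      if (grepl(paste0("^(?:", rows$pattern[r], ")$"), cue$surface,
                perl = TRUE, ignore.case = TRUE)) {
        dir <- rows$direction[r]
        break
      }
    }
    sc <- compute_scope(cue, doc, triggers, max_window, dir)
    if (!is.null(sc)) scopes[[length(scopes) + 1L]] <- sc
  }
  scopes
}

#' Assign Negated/Speculated attributes
#'
#' Concept-level semantics: an eligible entity (UMLS layers ANAT, CHEM,
#' DEVI, DISO, GENE, LIVB, PHYS, PROC) fully inside a scope receives the
#' cue's polarity attribute. With several covering scopes the nearest cue
#' wins; Negated beats Speculated at equal distance. At most one of
#' Negated/Speculated per entity.
#'
#' @param entities entity data.frame (the umls layer).
#' @param scopes list of scopes from [compute_scopes()].
#' @return Attribute data.frame targeting entity ids.
#' @export
assign_negspec <- function(entities, scopes) {
  if (!nrow(entities) || !length(scopes)) return(empty_attributes())
  elig <- entities[entities$label %in% negspec_eligible_labels(), , drop = FALSE]
  types <- character(0); targets <- character(0)
  for (i in seq_len(nrow(elig))) {
    best <- NULL; best_d <- Inf; best_neg <- FALSE
    for (sc in scopes) {
      if (elig$start[i] >= sc$start && elig$end[i] <= sc$end) {
        d <- if (elig$start[i] >= sc$cue_end) elig$start[i] - sc$cue_end
             else sc$cue_start - elig$end[i]
        is_neg <- sc$polarity == "negation"
        if (d < best_d || (d == best_d && is_neg && !best_neg)) {
          best <- sc; best_d <- d; best_neg <- is_neg
        }
      }
    }
    if (!is.null(best)) {
      types <- c(types, if (best$polarity == "negation") "Negated" else "Speculated")
      targets <- c(targets, elig$id[i])
    }
  }
  make_attributes(types, targets)
}
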