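# Character offsets throughout the package are 0-based, end-exclusive and
# counted in Unicode code points (the BRAT standoff convention), so that the
# .ann files written here load bit-exactly in the BRAT tool.

#' Extract a code-point slice from text
#'
#' @param text character scalar (UTF-8).
#' @param start,end 0-based, end-exclusive code-point offsets.
#' @return The substring `text[start:end)`.
#' @keywords internal
slice_text <- function(text, start, end) {
  substr(text, start + 1L, end)
}

#' Entity label vocabulary
#'
#' The closed set of entity labels recognised by the annotator: the UMLS
#' semantic groups (ANAT, CHEM, DISO, PROC, DEVI, GENE, PHYS, LIVB, ACTI),
#' TimeML-style temporal classes plus Age, medication classes, cue labels
#' and miscellaneous clinical classes.
#'
#' @return Character vector of valid labels.
#' @export
entity_label_vocab <- function() {
  c("ANAT", "CHEM", "DISO", "PROC", "DEVI", "GENE", "PHYS", "LIVB", "ACTI",
    "Date", "Duration", "Frequency", "Time", "Age",
    "Dose", "Route", "Form",
    "Neg_cue", "Spec_cue",
    "CONC", "Food_or_Drink", "Observation_or_Finding",
    "Quantifier_or_Qualifier", "Result_or_Value")
}

#' Attribute type vocabulary
#' @return Character vector of valid attribute types.
#' @export
attribute_type_vocab <- function() {
  c("Age", "Negated", "Speculated", "Contraindicated",
    "History_of", "Family_History_of", "Future", "Hypothetical",
    "Patient", "Family_member", "Other")
}

# UMLS semantic groups (dictionary layer labels)
umls_groups <- function() {
  c("ANAT", "CHEM", "DISO", "PROC", "DEVI", "GENE", "PHYS", "LIVB", "ACTI")
}

# Labels eligible for Negated/Speculated attributes
negspec_eligible_labels <- function() {
  c("ANAT", "CHEM", "DEVI", "DISO", "GENE", "LIVB", "PHYS", "PROC")
}

#' Map an entity label to its annotation layer
#'
#' Entities live in one of five layers (umls, temporal, medication, misc,
#' cues); overlap is forbidden within a layer but allowed across layers
#' (e.g. a Dose inside a PROC phrase).
#'
#' @param label character vector of entity labels.
#' @return character vector of layer names.
#' @export
label_layer <- function(label) {
  out <- rep(NA_character_, length(label))
  out[label %in% umls_groups()] <- "umls"
  out[label %in% c("Date", "Duration", "Frequency", "Time", "Age")] <- "temporal"
  out[label %in% c("Dose", "Route", "Form")] <- "medication"
  out[label %in% c("Neg_cue", "Spec_cue")] <- "cues"
  misc <- c("CONC", "Food_or_Drink", "Observation_or_Finding",
            "Quantifier_or_Qualifier", "Result_or_Value")
  out[label %in% misc] <- "misc"
  out
}

empty_entities <- function() {
  data.frame(id = character(), label = character(),
             start = integer(), end = integer(),
             surface = character(), layer = character(),
             source = character(), score = numeric(),
             codes = character(), stringsAsFactors = FALSE)
}

empty_attributes <- function() {
  data.frame(id = character(), type = character(), target = character(),
             stringsAsFactors = FALSE)
}

empty_sentences <- function() {
  data.frame(start = integer(), end = integer(), stringsAsFactors = FALSE)
}

empty_tokens <- function() {
  data.frame(sentence = integer(), start = integer(), end = integer(),
             surface = character(), lemma = character(), pos = character(),
             stringsAsFactors = FALSE)
}

#' Build an entity table
#'
#' @param label,start,end,surface parallel vectors describing entity spans.
#' @param source provenance: one of dictionary, rules, model, gold.
#' @param score optional confidence in `[0, 1]`.
#' @param codes normalization codes as `scheme:code` strings joined by `|`
#'   (e.g. `"UMLS:C0011849|SNOMEDCT:73211009"`), `""` for none.
#' @param id optional ids; generated as `E1..En` when omitted.
#' @return data.frame with one row per entity.
#' @export
make_entities <- function(label, start, end, surface,
                          source = "rules", score = NA_real_,
                          codes = "", id = NULL) {
  n <- length(label)
  if (n == 0L) return(empty_entities())
  if (is.null(id)) id <- paste0("E", seq_len(n))
  bad <- !label %in% entity_label_vocab()
  if (any(bad)) {
    stop("unknown entity label(s): ", paste(unique(label[bad]), collapse = ", "))
  }
  data.frame(id = id, label = label,
             start = as.integer(start), end = as.integer(end),
             surface = surface, layer = label_layer(label),
             source = rep_len(source, n), score = rep_len(score, n),
             codes = rep_len(codes, n), stringsAsFactors = FALSE)
}

#' Build an attribute table
#'
#' @param type attribute types (see [attribute_type_vocab()]).
#' @param target entity ids the attributes attach to.
#' @param id optional ids; generated as `A1..An` when omitted.
#' @return data.frame with one row per attribute.
#' @export
make_attributes <- function(type, target, id = NULL) {
  n <- length(type)
  if (n == 0L) return(empty_attributes())
  if (is.null(id)) id <- paste0("A", seq_len(n))
  bad <- !type %in% attribute_type_vocab()
  if (any(bad)) {
    stop("unknown attribute type(s): ", paste(unique(type[bad]), collapse = ", "))
  }
  data.frame(id = id, type = type, target = target, stringsAsFactors = FALSE)
}

#' Default character-substitution table
#'
#' Same-length substitutions for characters that routinely break downstream
#' tooling: curly quotes to straight quotes, non-breaking/thin spaces to
#' plain space, soft hyphen and typographic dashes to ASCII hyphen.
#' Each mapping replaces one code point with one code point, so raw and
#' normalized offsets stay identical.
#'
#' @return Named character vector mapping single characters to single
#'   characters.
#' @export
default_substitution_table <- function() {
  c(" " = " ",  # no-break space
    " " = " ",  # thin space
    " " = " ",  # narrow no-break space
    " " = " ",  # figure space
    "‘" = "'", "’" = "'",  # curly single quotes
    "“" = '"', "”" = '"',  # curly double quotes
    "«" = '"', "»" = '"',  # guillemets
    "­" = "-",  # soft hyphen
    "–" = "-", "—" = "-",  # en/em dash
    "−" = "-")  # minus sign
}

#' Normalize text by same-length character substitution
#'
#' Replaces problem characters one-for-one so that the normalized text has
#' exactly the same length (in code points) as the input; offsets into the
#' normalized text are therefore valid into the raw text too. The operation
#' is idempotent.
#'
#' @param raw character scalar.
#' @param substitution_table named character vector, single character to
#'   single character (default [default_substitution_table()]).
#' @return Normalized string of identical code-point length.
#' @export
normalize_text <- function(raw, substitution_table = default_substitution_table()) {
  if (length(substitution_table)) {
    if (any(nchar(names(substitution_table)) != 1L) ||
        any(nchar(substitution_table) != 1L)) {
      stop("substitution_table must map single characters to single characters")
    }
  }
  if (!nzchar(raw) || !length(substitution_table)) return(raw)
  # character-by-character gsub: chartr() maps bytes when old/new mix
  # multibyte and single-byte characters, which would corrupt the text
  out <- raw
  for (i in seq_along(substitution_table)) {
    out <- gsub(names(substitution_table)[i], substitution_table[[i]], out,
                fixed = TRUE)
  }
  out
}

#' Create a document
#'
#' A `clin_document` bundles the raw and normalized text with sentence and
#' token segmentation, entities and attributes. Offsets are 0-based,
#' end-exclusive code points.
#'
#' @param text input text (UTF-8).
#' @param doc_id document identifier.
#' @param substitution_table passed to [normalize_text()].
#' @return Object of class `clin_document`.
#' @export
clin_document <- function(text, doc_id = "doc",
                          substitution_table = default_substitution_table()) {
  raw <- enc2utf8(text)
  doc <- structure(list(
    doc_id = doc_id,
    raw_text = raw,
    text = normalize_text(raw, substitution_table),
    sentences = empty_sentences(),
    tokens = empty_tokens(),
    entities = empty_entities(),
    attributes = empty_attributes()
  ), class = "clin_document")
  doc
}

#' @export
print.clin_document <- function(x, ...) {
  cat(sprintf("<clin_document '%s': %d chars, %d sentences, %d entities, %d attributes>\n",
              x$doc_id, nchar(x$text), nrow(x$sentences),
              nrow(x$entities), nrow(x$attributes)))
  if (nrow(x$entities)) {
    tab <- table(x$entities$label)
    cat("  entities:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  invisible(x)
}

#' Default sentence splitter and tokenizer
#'
#' A dependency-free provider satisfying the tokenizer contract: given
#' normalized text it returns sentence spans and tokens with offsets, a
#' lemma (lowercased surface) and a coarse POS guess (NUM, PUNCT, WORD).
#' Sentences split after `.`, `!`, `?` or newline followed by whitespace
#' and an uppercase/opening character. Tokens are maximal runs of letters
#' or digits (decimal comma/dot kept inside numbers); every other
#' non-space character is its own token.
#'
#' @return A provider `function(text)` returning
#'   `list(sentences = data.frame(start, end), tokens = data.frame(sentence,
#'   start, end, surface, lemma, pos))`.
#' @export
default_tokenizer <- function() {
  function(text) {
    n <- nchar(text)
    if (n == 0L) {
      return(list(sentences = empty_sentences(), tokens = empty_tokens()))
    }
    # sentence boundaries: terminator + space(s) + sentence opener
    bound_re <- "(?<=[.!?…])\\s+(?=[\\p{Lu}¿¡\"'(\\[0-9])|\\n+"
    m <- gregexpr(bound_re, text, perl = TRUE)[[1]]
    starts <- 0L
    ends <- integer(0)
    if (m[1] != -1L) {
      for (k in seq_along(m)) {
        b_start <- m[k] - 1L                       # 0-based offset of break
        b_len <- attr(m, "match.length")[k]
        ends <- c(ends, b_start)
        starts <- c(starts, b_start + b_len)
      }
    }
    ends <- c(ends, n)
    # trim whitespace-only sentences
    keep <- logical(length(starts))
    for (k in seq_along(starts)) {
      keep[k] <- grepl("\\S", slice_text(text, starts[k], ends[k]), perl = TRUE)
    }
    starts <- starts[keep]; ends <- ends[keep]
    if (!length(starts)) {
      return(list(sentences = empty_sentences(), tokens = empty_tokens()))
    }
    # tighten sentence spans to non-space extent
    for (k in seq_along(starts)) {
      s_txt <- slice_text(text, starts[k], ends[k])
      lead <- regmatches(s_txt, regexpr("^\\s*", s_txt, perl = TRUE))
      trail <- regmatches(s_txt, regexpr("\\s*$", s_txt, perl = TRUE))
      starts[k] <- starts[k] + nchar(lead)
      ends[k] <- ends[k] - nchar(trail)
    }
    sent <- data.frame(start = starts, end = ends)
    tok_re <- "\\d+(?:[.,]\\d+)*|[\\p{L}\\p{M}]+(?:['’][\\p{L}\\p{M}]+)?|\\S"
    tok_list <- vector("list", nrow(sent))
    for (k in seq_len(nrow(sent))) {
      s_txt <- slice_text(text, sent$start[k], sent$end[k])
      tm <- gregexpr(tok_re, s_txt, perl = TRUE)[[1]]
      if (tm[1] == -1L) {
        tok_list[[k]] <- empty_tokens()
        next
      }
      t_start <- sent$start[k] + tm - 1L
      t_end <- t_start + attr(tm, "match.length")
      surf <- regmatches(s_txt, list(tm))[[1]]
      pos <- ifelse(grepl("^\\d", surf), "NUM",
                    ifelse(grepl("^[\\p{L}]", surf, perl = TRUE), "WORD", "PUNCT"))
      tok_list[[k]] <- data.frame(sentence = k, start = t_start, end = t_end,
                                  surface = surf, lemma = tolower(surf),
                                  pos = pos, stringsAsFactors = FALSE)
    }
    list(sentences = sent, tokens = do.call(rbind, tok_list))
  }
}

#' Segment a document into sentences and tokens
#'
#' Runs the injected tokenizer provider over `doc$text` and validates the
#' returned offsets against the text (every token surface must equal its
#' text slice).
#'
#' @param doc a [clin_document()].
#' @param provider a tokenizer provider (default [default_tokenizer()]).
#' @return The document with `sentences` and `tokens` populated.
#' @export
segment <- function(doc, provider = default_tokenizer()) {
  stopifnot(inherits(doc, "clin_document"))
  res <- provider(doc$text)
  n <- nchar(doc$text)
  toks <- res$tokens
  if (nrow(toks)) {
    if (any(toks$start < 0L) || any(toks$end > n) || any(toks$start >= toks$end)) {
      stop("tokenizer provider returned offsets out of bounds")
    }
    got <- vapply(seq_len(nrow(toks)),
                  function(i) slice_text(doc$text, toks$start[i], toks$end[i]),
                  character(1))
    if (!identical(got, toks$surface)) {
      stop("tokenizer provider surfaces do not match text slices")
    }
  }
  doc$sentences <- res$sentences
  doc$tokens <- toks
  doc
}

is_segmented <- function(doc) nrow(doc$sentences) > 0L || nchar(doc$text) == 0L

#' Validate document invariants
#'
#' Checks offset bounds, surface/slice agreement, label and attribute-type
#' vocabulary membership, attribute targets, within-layer non-overlap and
#' the one-attribute-per-type-per-entity rule. Never raises; returns a
#' data.frame of violations (zero rows when the document is well formed).
#'
#' @param doc a [clin_document()].
#' @return data.frame with columns `id` and `rule`.
#' @export
validate_document <- function(doc) {
  v_id <- character(0); v_rule <- character(0)
  add <- function(id, rule) {
    v_id <<- c(v_id, id); v_rule <<- c(v_rule, rule)
  }
  n <- nchar(doc$text)
  if (nchar(doc$raw_text) != n) add(doc$doc_id, "raw/normalized length mismatch")
  e <- doc$entities
  for (i in seq_len(nrow(e))) {
    if (is.na(e$start[i]) || is.na(e$end[i]) ||
        e$start[i] < 0L || e$end[i] > n || e$start[i] >= e$end[i]) {
      add(e$id[i], "offsets out of bounds")
      next
    }
    if (!identical(slice_text(doc$text, e$start[i], e$end[i]), e$surface[i])) {
      add(e$id[i], "surface does not match text slice")
    }
    if (!e$label[i] %in% entity_label_vocab()) add(e$id[i], "unknown label")
  }
  # within-layer overlap
  if (nrow(e) > 1L) {
    for (lay in unique(e$layer)) {
      sub <- e[e$layer == lay, , drop = FALSE]
      sub <- sub[order(sub$start, sub$end), , drop = FALSE]
      if (nrow(sub) > 1L) {
        # co-located (span-identical) entities are tolerated: an entry in
        # several semantic groups emits one entity per group on one span
        for (i in 2:nrow(sub)) {
          prev <- i - 1L
          same_span <- sub$start[i] == sub$start[prev] &&
            sub$end[i] == sub$end[prev]
          if (sub$start[i] < sub$end[prev] && !same_span) {
            add(sub$id[i], paste0("overlap within layer ", lay))
          }
        }
      }
    }
  }
  a <- doc$attributes
  for (i in seq_len(nrow(a))) {
    if (!a$type[i] %in% attribute_type_vocab()) add(a$id[i], "unknown attribute type")
    if (!a$target[i] %in% e$id) add(a$id[i], "attribute targets missing entity")
  }
  if (nrow(a) > 1L) {
    key <- paste(a$target, a$type)
    dup <- duplicated(key)
    for (i in which(dup)) add(a$id[i], "duplicate attribute type on entity")
  }
  tk <- doc$tokens
  for (i in seq_len(nrow(tk))) {
    if (tk$start[i] < 0L || tk$end[i] > n ||
        !identical(slice_text(doc$text, tk$start[i], tk$end[i]), tk$surface[i])) {
      add(doc$doc_id, "token offsets invalid")
      break
    }
  }
  data.frame(id = v_id, rule = v_rule, stringsAsFactors = FALSE)
}

# Append entities to a document, assigning fresh ids after existing ones.
add_entities <- function(doc, ents) {
  if (!nrow(ents)) return(doc)
  k <- nrow(doc$entities)
  ents$id <- paste0("E", k + seq_len(nrow(ents)))
  doc$entities <- rbind(doc$entities, ents)
  doc
}

add_attributes <- function(doc, attrs) {
  if (!nrow(attrs)) return(doc)
  k <- nrow(doc$attributes)
  attrs$id <- paste0("A", k + seq_len(nrow(attrs)))
  # at most one attribute of a given type per entity: first assignment wins
  key_old <- paste(doc$attributes$target, doc$attributes$type)
  key_new <- paste(attrs$target, attrs$type)
  attrs <- attrs[!key_new %in% key_old & !duplicated(key_new), , drop = FALSE]
  doc$attributes <- rbind(doc$attributes, attrs)
  doc
}

# Tokens belonging to sentence k
sentence_tokens <- function(doc, k) {
  doc$tokens[doc$tokens$sentence == k, , drop = FALSE]
}
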