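# Shared fixtures and independent oracles for the test suite.

mk_doc <- function(text) segment(clin_document(text))

test_lexicon <- local({
  lex <- NULL
  function() {
    if (is.null(lex)) lex <<- toy_lexicon()
    lex
  }
})

annotate_fixture <- function(text, ...) {
  annotate(text, lexicon = test_lexicon(), ...)
}

entity_key <- function(entities) {
  sort(paste(entities$start, entities$end, entities$label))
}

attr_key <- function(doc) {
  m <- merge(doc$attributes, doc$entities, by.x = "target", by.y = "id")
  sort(paste(m$type, m$start, m$end, m$label))
}

# ---- independent oracle: dictionary matcher ------------------------------
# Enumerates every token n-gram that matches a variant table built directly
# from the raw lexicon TSV rows, then keeps maximal non-overlapping matches
# leftmost-first (longest at each position). Fully independent of the
# package's index/lookup machinery.
oracle_variant_table <- function() {
  rows <- strsplit(readLines(gen_toy_lexicon(), encoding = "UTF-8"), "\t")
  rows <- rows[-1]
  abbr <- list(); norm <- list()
  for (r in rows) {
    variants <- c(r[1], if (nzchar(r[2])) strsplit(r[2], "|", fixed = TRUE)[[1]])
    groups <- strsplit(r[3], "|", fixed = TRUE)[[1]]
    for (v in variants) {
      if (r[6] == "1") {
        abbr[[v]] <- unique(c(abbr[[v]], groups))
      } else {
        key <- chartr("áéíóúü", "aeiouu", tolower(v))
        norm[[key]] <- unique(c(norm[[key]], groups))
      }
    }
  }
  list(abbr = abbr, norm = norm)
}

oracle_match <- function(doc, tab, include_groups = NULL,
                         excluded_groups = character(0)) {
  out <- list()
  for (k in seq_len(nrow(doc$sentences))) {
    toks <- doc$tokens[doc$tokens$sentence == k, , drop = FALSE]
    n <- nrow(toks)
    cands <- list()
    for (i in seq_len(n)) {
      for (len in seq_len(n - i + 1L)) {
        idx <- i:(i + len - 1L)
        raw <- paste(toks$surface[idx], collapse = " ")
        folded <- chartr("áéíóúü", "aeiouu", tolower(raw))
        groups <- unique(c(tab$abbr[[raw]], tab$norm[[folded]]))
        if (!is.null(include_groups)) groups <- intersect(groups, include_groups)
        groups <- setdiff(groups, excluded_groups)
        if (length(groups)) {
          cands[[length(cands) + 1L]] <- list(i = i, len = len, groups = groups)
        }
      }
    }
    # maximal non-overlapping, leftmost-first, longest at each position
    taken <- rep(FALSE, n)
    pos <- 1L
    while (pos <= n) {
      here <- Filter(function(c) c$i == pos, cands)
      if (!length(here)) { pos <- pos + 1L; next }
      best <- here[[which.max(vapply(here, `[[`, integer(1), "len"))]]
      idx <- best$i:(best$i + best$len - 1L)
      for (g in best$groups) {
        out[[length(out) + 1L]] <- data.frame(
          start = toks$start[idx[1]], end = toks$end[idx[best$len]],
          label = g, stringsAsFactors = FALSE)
      }
      pos <- pos + best$len
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(),
                      label = character(), stringsAsFactors = FALSE))
  }
  unique(do.call(rbind, out))
}

# ---- independent oracle: strict scorer -----------------------------------
oracle_strict <- function(gold, pred) {
  used <- rep(FALSE, nrow(pred))
  tp <- 0L
  for (i in seq_len(nrow(gold))) {
    for (j in seq_len(nrow(pred))) {
      if (!used[j] && gold$start[i] == pred$start[j] &&
          gold$end[i] == pred$end[j] && gold$label[i] == pred$label[j]) {
        used[j] <- TRUE; tp <- tp + 1L
        break
      }
    }
  }
  c(tp = tp, fp = nrow(pred) - tp, fn = nrow(gold) - tp)
}

# ---- independent oracle: scope assignment --------------------------------
# tests all entity x scope containments, picks nearest cue, negation beats
# speculation on ties
oracle_assign <- function(entities, scopes) {
  elig_labels <- c("ANAT", "CHEM", "DEVI", "DISO", "GENE", "LIVB", "PHYS",
                   "PROC")
  out <- list()
  for (i in seq_len(nrow(entities))) {
    if (!entities$label[i] %in% elig_labels) next
    cover <- Filter(function(sc) {
      entities$start[i] >= sc$start && entities$end[i] <= sc$end
    }, scopes)
    if (!length(cover)) next
    dist <- vapply(cover, function(sc) {
      if (entities$start[i] >= sc$cue_end) entities$start[i] - sc$cue_end
      else sc$cue_start - entities$end[i]
    }, numeric(1))
    cover <- cover[dist == min(dist)]
    pol <- vapply(cover, `[[`, character(1), "polarity")
    type <- if ("negation" %in% pol) "Negated" else "Speculated"
    out[[length(out) + 1L]] <- c(target = entities$id[i], type = type)
  }
  if (!length(out)) return(character(0))
  sort(vapply(out, function(x) paste(x[["target"]], x[["type"]]), character(1)))
}

# random entity sets over a virtual text, for scorer oracles
random_entity_set <- function(n, text_len = 60L, labels = c("DISO", "CHEM", "PROC")) {
  if (n == 0L) return(make_entities(character(0), integer(0), integer(0), character(0)))
  start <- sample.int(text_len - 3L, n, replace = TRUE) - 1L
  len <- sample(1:5, n, replace = TRUE)
  make_entities(sample(labels, n, replace = TRUE), start,
                pmin(start + len, text_len),
                surface = strrep("x", len))
}
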