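# Pluggable token-classification backend. An adapter receives sentences
# as token lists and returns one BIO label and one confidence per input
# token (the adapter owns any subword splitting; first-subword convention
# keeps the pipeline model-agnostic). Decoded spans are merged with the
# dictionary output under a configurable policy.

#' Decode BIO labels into entity spans
#'
#' Maximal B-I runs become entities. Invalid transitions are repaired:
#' `I-X` after `O`, at sentence start, or after a different class is
#' treated as `B-X`.
#'
#' @param tokens token data.frame (one sentence or whole document).
#' @param labels character vector of BIO labels, same length as tokens.
#' @param text the document text the token offsets index into.
#' @param source provenance recorded on the entities (default "model").
#' @param scores optional per-token confidences; an entity's score is the
#'   minimum over its tokens.
#' @return Entity data.frame.
#' @export
bio_to_spans <- function(tokens, labels, text, source = "model",
                         scores = NULL) {
  if (nrow(tokens) != length(labels)) {
    stop("bio_to_spans: ", length(labels), " labels for ", nrow(tokens),
         " tokens")
  }
  if (!nrow(tokens)) return(empty_entities())
  lab <- character(0); st <- integer(0); en <- integer(0); sc <- numeric(0)
  cur <- NULL
  flush <- function() {
    if (!is.null(cur)) {
      lab <<- c(lab, cur$label); st <<- c(st, cur$start); en <<- c(en, cur$end)
      sc <<- c(sc, cur$score)
    }
    cur <<- NULL
  }
  for (i in seq_len(nrow(tokens))) {
    l <- labels[i]
    new_sent <- i > 1L && tokens$sentence[i] != tokens$sentence[i - 1L]
    if (l == "O" || is.na(l)) { flush(); next }
    if (!grepl("^[BI]-", l)) stop("bio_to_spans: invalid label ", l)
    cls <- substring(l, 3L)
    s_i <- if (is.null(scores)) NA_real_ else scores[i]
    continues <- startsWith(l, "I-") && !is.null(cur) && cur$label == cls &&
      !new_sent
    if (continues) {
      cur$end <- tokens$end[i]
      cur$score <- min(cur$score, s_i, na.rm = FALSE)
    } else {
      flush()  # I- after O / other class repaired as B-
      cur <- list(label = cls, start = tokens$start[i], end = tokens$end[i],
                  score = s_i)
    }
  }
  flush()
  make_entities(lab, st, en,
                vapply(seq_along(st), function(i) slice_text(text, st[i], en[i]),
                       character(1)),
                source = source, score = sc)
}

#' Build a deterministic mock model adapter
#'
#' For tests and offline pipelines: a lookup from token sequences (keys
#' are surfaces joined by single spaces) to BIO label sequences. Unknown
#' tokens get `O`; every score is 1. Longest lookup key wins,
#' left-to-right.
#'
#' @param lookup named list: `"diabetes mellitus"` -> `c("B-DISO",
#'   "I-DISO")`, or a TSV path with columns `tokens` and `labels`
#'   (space-separated within each column).
#' @return An adapter `function(sentences)` where `sentences` is a list of
#'   character vectors; returns a list of `list(labels, scores)`.
#' @export
make_mock_adapter <- function(lookup = list()) {
  if (is.character(lookup) && length(lookup) == 1L) {
    lines <- read_lines_utf8(lookup)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    lookup <- stats::setNames(
      lapply(parts, function(p) strsplit(p[2], " ", fixed = TRUE)[[1]]),
      vapply(parts, `[[`, character(1), 1))
  }
  for (k in names(lookup)) {
    labs <- lookup[[k]]
    if (any(!grepl("^O$|^[BI]-", labs))) {
      stop("mock adapter: invalid BIO label for key '", k, "'")
    }
  }
  key_lens <- if (length(lookup)) {
    lengths(strsplit(names(lookup), " ", fixed = TRUE))
  } else integer(0)
  max_len <- if (length(key_lens)) max(key_lens) else 1L
  function(sentences) {
    lapply(sentences, function(toks) {
      n <- length(toks)
      labels <- rep("O", n)
      i <- 1L
      while (i <= n) {
        hit <- 0L
        for (len in seq(min(max_len, n - i + 1L), 1L)) {
          key <- paste(toks[i:(i + len - 1L)], collapse = " ")
          if (!is.null(lookup[[key]])) { hit <- len; break }
        }
        if (hit > 0L) {
          labels[i:(i + hit - 1L)] <- lookup[[paste(toks[i:(i + hit - 1L)],
                                                    collapse = " ")]]
          i <- i + hit
        } else i <- i + 1L
      }
      list(labels = labels, scores = rep(1, n))
    })
  }
}

# run an adapter over a segmented document and decode spans
run_adapter <- function(doc, adapter) {
  if (!nrow(doc$tokens)) return(empty_entities())
  sents <- split(doc$tokens$surface, doc$tokens$sentence)
  res <- adapter(sents)
  labels <- unlist(lapply(res, `[[`, "labels"), use.names = FALSE)
  scores <- unlist(lapply(res, `[[`, "scores"), use.names = FALSE)
  if (length(labels) != nrow(doc$tokens)) {
    stop("model adapter contract error: label count != token count")
  }
  bio_to_spans(doc$tokens, labels, doc$text, source = "model",
               scores = scores)
}

#' Default hybrid merge policy
#' @param precedence `"model_first"` or `"dictionary_first"`.
#' @param dictionary_only_groups groups only the dictionary recognises
#'   (default ACTI).
#' @param enrich_codes copy dictionary codes onto span-identical model
#'   entities (default TRUE).
#' @return A merge-policy list.
#' @export
merge_policy <- function(precedence = c("model_first", "dictionary_first"),
                         dictionary_only_groups = "ACTI",
                         enrich_codes = TRUE) {
  list(precedence = match.arg(precedence),
       dictionary_only_groups = dictionary_only_groups,
       enrich_codes = isTRUE(enrich_codes))
}

#' Merge model and dictionary entities
#'
#' Under `model_first`: span- and label-identical pairs collapse to the
#' model entity carrying the dictionary codes (when `enrich_codes`);
#' overlap conflicts keep the model entity; dictionary entities in
#' `dictionary_only_groups` or not overlapping any model entity are
#' added. `dictionary_first` mirrors the rule. The result is
#' non-overlapping within the layer.
#'
#' @param model_entities,dict_entities entity data.frames from the same
#'   layer.
#' @param policy a [merge_policy()].
#' @return Merged entity data.frame.
#' @export
merge_hybrid <- function(model_entities, dict_entities,
                         policy = merge_policy()) {
  if (policy$precedence == "dictionary_first") {
    return(merge_hybrid(dict_entities, model_entities,
                        merge_policy("model_first",
                                     policy$dictionary_only_groups,
                                     policy$enrich_codes)))
  }
  win <- model_entities
  lose <- dict_entities
  if (nrow(win) && nrow(lose) && policy$enrich_codes) {
    for (i in seq_len(nrow(win))) {
      same <- which(lose$start == win$start[i] & lose$end == win$end[i] &
                    lose$label == win$label[i])
      if (length(same) && !nzchar(win$codes[i])) {
        win$codes[i] <- lose$codes[same[1]]
      }
    }
  }
  keep_lose <- logical(nrow(lose))
  for (j in seq_len(nrow(lose))) {
    dict_only <- lose$label[j] %in% policy$dictionary_only_groups
    overlaps <- nrow(win) > 0L &&
      any(lose$start[j] < win$end & lose$end[j] > win$start)
    keep_lose[j] <- dict_only || !overlaps
  }
  out <- rbind(win, lose[keep_lose, , drop = FALSE])
  if (!nrow(out)) return(empty_entities())
  # final within-layer overlap resolution (dictionary-only entities can
  # still collide with model spans): model first, then dictionary
  out$priority <- c(rep(2L, nrow(win)), rep(1L, sum(keep_lose)))
  dict_only_flag <- out$label %in% policy$dictionary_only_groups &
    out$source == "dictionary"
  out$priority[dict_only_flag] <- 3L
  kept <- resolve_overlaps(out)
  kept$priority <- NULL
  kept$id <- paste0("E", seq_len(nrow(kept)))
  rownames(kept) <- NULL
  kept
}
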