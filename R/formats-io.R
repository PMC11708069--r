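# Interchange formats: CoNLL-style BIO (two columns, tab-separated, blank
# line between sentences), BRAT standoff (.txt/.ann pair) and JSON.
# BRAT offsets are code points, matching the core convention, so files
# load bit-exactly in the BRAT tool.

#' Convert a document layer to BIO rows
#'
#' One label per token; entity tokens get `B-label` then `I-label`.
#' Entities not aligned to token boundaries are snapped outward to the
#' covering tokens (with a warning); co-located duplicate spans keep the
#' first entity.
#'
#' @param doc a segmented [clin_document()].
#' @param layer which entity layer to encode (default "umls").
#' @return data.frame with columns `sentence`, `token`, `label`.
#' @export
to_bio <- function(doc, layer = "umls") {
  toks <- doc$tokens
  labels <- rep("O", nrow(toks))
  ents <- doc$entities[doc$entities$layer == layer, , drop = FALSE]
  ents <- ents[order(ents$start, ents$end), , drop = FALSE]
  ents <- ents[!duplicated(paste(ents$start, ents$end)), , drop = FALSE]
  snapped <- 0L
  for (i in seq_len(nrow(ents))) {
    idx <- which(toks$end > ents$start[i] & toks$start < ents$end[i])
    if (!length(idx)) next
    if (toks$start[idx[1]] != ents$start[i] ||
        toks$end[idx[length(idx)]] != ents$end[i]) snapped <- snapped + 1L
    if (any(labels[idx] != "O")) next  # already claimed (overlap guard)
    labels[idx] <- c(paste0("B-", ents$label[i]),
                     rep(paste0("I-", ents$label[i]), length(idx) - 1L))
  }
  if (snapped > 0L) {
    warning(snapped, " entity span(s) snapped outward to token boundaries")
  }
  data.frame(sentence = toks$sentence, token = toks$surface,
             label = labels, stringsAsFactors = FALSE)
}

#' Reconstruct entities from BIO rows
#'
#' Inverse of [to_bio()] up to snapped spans; invalid `I-` transitions
#' are repaired as in [bio_to_spans()].
#'
#' @param rows data.frame from [to_bio()] (or read from a BIO file).
#' @param doc the segmented document the rows were produced from.
#' @param source provenance for the rebuilt entities (default "gold").
#' @return Entity data.frame.
#' @export
from_bio <- function(rows, doc, source = "gold") {
  bad <- !grepl("^O$|^[BI]-", rows$label)
  if (any(bad)) stop("from_bio: unknown label string '", rows$label[bad][1], "'")
  bad_cls <- grepl("^[BI]-", rows$label) &
    !substring(rows$label, 3L) %in% entity_label_vocab()
  if (any(bad_cls)) {
    stop("from_bio: unknown entity class in '", rows$label[bad_cls][1], "'")
  }
  bio_to_spans(doc$tokens, rows$label, doc$text, source = source)
}

#' Write / read BIO files (CoNLL dialect)
#'
#' Two tab-separated columns (token, label), one token per line, blank
#' line between sentences.
#'
#' @param rows data.frame from [to_bio()].
#' @param path output file.
#' @export
write_bio <- function(rows, path) {
  out <- character(0)
  for (k in unique(rows$sentence)) {
    sub <- rows[rows$sentence == k, , drop = FALSE]
    out <- c(out, paste(sub$token, sub$label, sep = "\t"), "")
  }
  writeLines(out, path, useBytes = FALSE)
  invisible(path)
}

#' @rdname write_bio
#' @return `read_bio()`: a data.frame with columns `sentence`, `token`,
#'   `label`.
#' @export
read_bio <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sent <- 1L
  rows <- list()
  for (ln in lines) {
    if (!nzchar(trimws(ln))) {
      if (length(rows) && rows[[length(rows)]]$sentence == sent) sent <- sent + 1L
      next
    }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 2L) stop("read_bio: malformed line: ", ln)
    rows[[length(rows) + 1L]] <- data.frame(sentence = sent, token = f[1],
                                            label = f[2],
                                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(sentence = integer(), token = character(),
                      label = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

brat_safe_label <- function(label) gsub("/", "_or_", label, fixed = TRUE)

#' Write a document as a BRAT standoff pair
#'
#' Writes `<stem>.txt` (the normalized text) and `<stem>.ann` with the
#' line grammar: entities `T{n}\tLabel start end\tsurface`, binary
#' attributes `A{n}\tType T{m}`, normalizations
#' `N{n}\tReference T{m} scheme:code\tsurface`.
#'
#' @param doc a [clin_document()].
#' @param stem output path without extension.
#' @return Invisibly, the `.ann` path.
#' @export
write_brat <- function(doc, stem) {
  txt_path <- paste0(stem, ".txt")
  ann_path <- paste0(stem, ".ann")
  con <- file(txt_path, open = "w", encoding = "UTF-8")
  cat(doc$text, file = con, sep = "")
  close(con)
  lines <- character(0)
  e <- doc$entities
  tmap <- stats::setNames(sprintf("T%d", seq_len(nrow(e))), e$id)
  for (i in seq_len(nrow(e))) {
    lines <- c(lines, sprintf("%s\t%s %d %d\t%s", tmap[[e$id[i]]],
                              brat_safe_label(e$label[i]),
                              e$start[i], e$end[i], e$surface[i]))
  }
  a <- doc$attributes
  for (i in seq_len(nrow(a))) {
    if (!a$target[i] %in% names(tmap)) next
    lines <- c(lines, sprintf("A%d\t%s %s", i, a$type[i], tmap[[a$target[i]]]))
  }
  n_id <- 0L
  for (i in seq_len(nrow(e))) {
    for (code in split_pipe(e$codes[i])) {
      n_id <- n_id + 1L
      lines <- c(lines, sprintf("N%d\tReference %s %s\t%s", n_id,
                                tmap[[e$id[i]]], code, e$surface[i]))
    }
  }
  con <- file(ann_path, open = "w", encoding = "UTF-8")
  writeLines(lines, con)
  close(con)
  invisible(ann_path)
}

#' Read a BRAT standoff pair into a document
#'
#' @param txt_path path to the `.txt` file.
#' @param ann_path path to the `.ann` file (default: same stem).
#' @param doc_id document id (default: the file stem).
#' @return A segmented [clin_document()] with entities (source "gold")
#'   and attributes. Raises an integrity error when an `.ann` span does
#'   not match its `.txt` slice.
#' @export
read_brat <- function(txt_path, ann_path = sub("\\.txt$", ".ann", txt_path),
                      doc_id = sub("\\.txt$", "", basename(txt_path))) {
  text <- paste(readLines(txt_path, encoding = "UTF-8", warn = FALSE),
                collapse = "\n")
  doc <- clin_document(text, doc_id = doc_id,
                       substitution_table = character(0))
  doc <- segment(doc)
  lines <- readLines(ann_path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  t_ids <- character(0)
  labs <- character(0); sts <- integer(0); ens <- integer(0); surfs <- character(0)
  codes <- list()
  attrs_type <- character(0); attrs_target <- character(0)
  for (ln in lines) {
    kind <- substr(ln, 1, 1)
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (kind == "T") {
      mid <- strsplit(f[2], " ", fixed = TRUE)[[1]]
      st <- as.integer(mid[2]); en <- as.integer(mid[3])
      surf <- f[3]
      if (!identical(slice_text(doc$text, st, en), surf)) {
        stop("brat integrity error: span ", f[1], " does not match text slice")
      }
      t_ids <- c(t_ids, f[1])
      labs <- c(labs, mid[1]); sts <- c(sts, st); ens <- c(ens, en)
      surfs <- c(surfs, surf)
      codes[[f[1]]] <- character(0)
    } else if (kind == "A") {
      mid <- strsplit(f[2], " ", fixed = TRUE)[[1]]
      attrs_type <- c(attrs_type, mid[1]); attrs_target <- c(attrs_target, mid[2])
    } else if (kind == "N") {
      mid <- strsplit(f[2], " ", fixed = TRUE)[[1]]
      codes[[mid[2]]] <- c(codes[[mid[2]]], mid[3])
    }
  }
  ents <- make_entities(labs, sts, ens, surfs, source = "gold",
                        codes = vapply(t_ids, function(t) {
                          paste(codes[[t]], collapse = "|")
                        }, character(1)),
                        id = t_ids)
  doc$entities <- ents
  doc$attributes <- make_attributes(attrs_type, attrs_target)
  doc
}

#' Serialize a document to JSON
#'
#' Schema: `{doc_id, text, entities: [{id, label, start, end, text,
#' codes, source}], attributes: [{id, type, target}]}` with stable key
#' order and UTF-8 text; codes are `scheme:code` strings.
#'
#' @param doc a [clin_document()].
#' @param path optional output file; when NULL the JSON string is
#'   returned.
#' @return JSON string (class `json`), or the path invisibly.
#' @export
doc_to_json <- function(doc, path = NULL) {
  e <- doc$entities
  entities <- lapply(seq_len(nrow(e)), function(i) {
    list(id = e$id[i], label = e$label[i], start = e$start[i], end = e$end[i],
         text = e$surface[i], codes = as.list(split_pipe(e$codes[i])),
         source = e$source[i])
  })
  a <- doc$attributes
  attributes <- lapply(seq_len(nrow(a)), function(i) {
    list(id = a$id[i], type = a$type[i], target = a$target[i])
  })
  obj <- list(doc_id = doc$doc_id, text = doc$text,
              entities = entities, attributes = attributes)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null")
  if (!is.null(path)) {
    writeLines(js, path, useBytes = FALSE)
    return(invisible(path))
  }
  js
}

#' Parse a JSON document produced by [doc_to_json()]
#'
#' @param json JSON string or file path.
#' @return A segmented [clin_document()].
#' @export
doc_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  doc <- clin_document(obj$text, doc_id = obj$doc_id,
                       substitution_table = character(0))
  doc <- segment(doc)
  if (length(obj$entities)) {
    doc$entities <- make_entities(
      vapply(obj$entities, `[[`, character(1), "label"),
      vapply(obj$entities, `[[`, numeric(1), "start"),
      vapply(obj$entities, `[[`, numeric(1), "end"),
      vapply(obj$entities, `[[`, character(1), "text"),
      source = vapply(obj$entities, `[[`, character(1), "source"),
      codes = vapply(obj$entities, function(e) {
        paste(unlist(e$codes), collapse = "|")
      }, character(1)),
      id = vapply(obj$entities, `[[`, character(1), "id"))
  }
  if (length(obj$attributes)) {
    doc$attributes <- make_attributes(
      vapply(obj$attributes, `[[`, character(1), "type"),
      vapply(obj$attributes, `[[`, character(1), "target"),
      id = vapply(obj$attributes, `[[`, character(1), "id"))
  }
  doc
}
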