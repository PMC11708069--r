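# Three-stage annotation pipeline. Stage 1: normalization, segmentation
# and UMLS-group NER (dictionary, model adapter, or hybrid merge) with an
# exceptions list. Stage 2 (each component toggleable): temporal,
# medication and miscellaneous entities, negation/speculation cues and
# concept-level attributes, temporality/experiencer/contraindication
# attributes. Stage 3: serialization (JSON or BRAT), handled by the
# writers.

#' Default pipeline configuration
#'
#' @param backend `"dict"`, `"model"` or `"hybrid"`.
#' @param norm normalization scheme kept on entity codes: `"umls"`,
#'   `"snomed"` or `"none"`.
#' @param lexicon use the dictionary at all (stage 1 and misc lexicon
#'   classes).
#' @param temporal,medication,misc,negspec,attributes stage-2 toggles.
#' @param excluded_groups semantic groups suppressed in stage 1 output.
#' @param output `"json"` or `"ann"` (batch serialization format).
#' @param max_window negation/speculation scope window in tokens.
#' @param future_heuristic detect simple-future verb forms for the Future
#'   attribute.
#' @return named list of options.
#' @export
default_config <- function(backend = "dict", norm = "umls", lexicon = TRUE,
                           temporal = TRUE, medication = TRUE, misc = TRUE,
                           negspec = TRUE, attributes = TRUE,
                           excluded_groups = character(0),
                           output = "json", max_window = 6L,
                           future_heuristic = TRUE) {
  list(backend = backend, norm = norm, lexicon = lexicon,
       temporal = temporal, medication = medication, misc = misc,
       negspec = negspec, attributes = attributes,
       excluded_groups = excluded_groups, output = output,
       max_window = as.integer(max_window),
       future_heuristic = future_heuristic)
}

#' Read a flat key=value configuration file
#'
#' INI-style: one `key = value` per line, `#` comments. Boolean values:
#' on/off/true/false/1/0. `excluded_groups` is comma-separated. Unknown
#' keys raise a configuration error listing them.
#'
#' @param path config file.
#' @return config list (see [default_config()]).
#' @export
read_config <- function(path) {
  lines <- read_lines_utf8(path)
  cfg <- default_config()
  known <- names(cfg)
  unknown <- character(0)
  as_bool <- function(v) tolower(v) %in% c("on", "true", "yes", "1")
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("config: malformed line: ", ln)
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    if (!key %in% known) { unknown <- c(unknown, key); next }
    cfg[[key]] <- switch(key,
      backend = , norm = , output = tolower(val),
      excluded_groups = trimws(strsplit(val, ",", fixed = TRUE)[[1]]),
      max_window = as.integer(val),
      as_bool(val))
  }
  if (length(unknown)) {
    stop("config: unknown keys: ", paste(unknown, collapse = ", "))
  }
  cfg
}

# bundle of loaded resources, cached per session
pipeline_resources <- function(lexicon = NULL) {
  if (is.null(.res_cache$bundle)) {
    .res_cache$bundle <- list(
      temporal_rules = load_temporal_rules(),
      med_terms = load_med_terms(),
      triggers = load_triggers(),
      attr_resources = load_attr_resources(),
      qualifiers = read_term_list(res_path("qualifiers.txt")))
  }
  b <- .res_cache$bundle
  b$lexicon <- lexicon
  b
}

#' Run the annotation pipeline on one text
#'
#' @param text input text (UTF-8) or a [clin_document()].
#' @param config a [default_config()]-style list.
#' @param lexicon a [load_lexicon()] result (required when
#'   `config$lexicon` or misc lexicon classes are wanted).
#' @param adapter model adapter (required for backend "model"/"hybrid").
#' @param provider tokenizer provider.
#' @param doc_id document id.
#' @return An annotated [clin_document()].
#' @export
annotate <- function(text, config = default_config(), lexicon = NULL,
                     adapter = NULL, provider = default_tokenizer(),
                     doc_id = "doc") {
  extra <- setdiff(names(config), names(default_config()))
  if (length(extra)) {
    stop("config: unknown keys: ", paste(extra, collapse = ", "))
  }
  res <- pipeline_resources(lexicon)
  doc <- if (inherits(text, "clin_document")) text
         else clin_document(text, doc_id = doc_id)
  doc <- segment(doc, provider)
  if (nchar(doc$text) == 0L) return(doc)

  # ---- stage 1: UMLS-group entities ----
  dict_ents <- empty_entities()
  if (config$lexicon && !is.null(lexicon) && config$backend != "model") {
    dict_ents <- match_entities(doc, lexicon,
                                excluded_groups = config$excluded_groups,
                                include_groups = umls_groups())
  }
  umls_ents <- dict_ents
  if (config$backend %in% c("model", "hybrid")) {
    if (is.null(adapter)) stop("backend '", config$backend,
                               "' requires a model adapter")
    model_ents <- run_adapter(doc, adapter)
    model_ents <- model_ents[model_ents$label %in% umls_groups() &
                               !model_ents$label %in% config$excluded_groups, ,
                             drop = FALSE]
    umls_ents <- if (config$backend == "hybrid") {
      merge_hybrid(model_ents, dict_ents, merge_policy())
    } else model_ents
  }
  if (config$norm %in% c("umls", "snomed") && !is.null(lexicon)) {
    scheme <- if (config$norm == "umls") "UMLS" else "SNOMEDCT"
    umls_ents <- normalize_entities(umls_ents, lexicon, scheme)
  } else if (config$norm == "none") {
    umls_ents$codes <- rep("", nrow(umls_ents))
  }
  doc <- add_entities(doc, umls_ents)

  # ---- stage 2 ----
  if (isTRUE(config$temporal)) {
    doc <- add_entities(doc, tag_temporal(doc, res$temporal_rules))
  }
  if (isTRUE(config$medication)) {
    doc <- add_entities(doc, tag_dose(doc, res$med_terms$units))
    med <- rbind(tag_route(doc, res$med_terms), tag_form(doc, res$med_terms))
    # within-layer: drop route/form spans colliding with a Dose
    dose <- doc$entities[doc$entities$label == "Dose", , drop = FALSE]
    if (nrow(med) && nrow(dose)) {
      clash <- vapply(seq_len(nrow(med)), function(i) {
        any(med$start[i] < dose$end & med$end[i] > dose$start)
      }, logical(1))
      med <- med[!clash, , drop = FALSE]
    }
    doc <- add_entities(doc, med)
  }
  if (isTRUE(config$misc)) {
    misc <- rbind(tag_result_value(doc, res$med_terms$units),
                  tag_quantifier(doc, res$qualifiers))
    if (config$lexicon && !is.null(lexicon)) {
      mlex <- tag_misc_lexicon(doc, lexicon)
      if (config$norm %in% c("umls", "snomed")) {
        scheme <- if (config$norm == "umls") "UMLS" else "SNOMEDCT"
        mlex <- normalize_entities(mlex, lexicon, scheme)
      } else {
        mlex$codes <- rep("", nrow(mlex))
      }
      misc <- rbind(misc, mlex)
    }
    # cross-layer rule: Dose wins over Result_or_Value on overlap
    dose <- doc$entities[doc$entities$label == "Dose", , drop = FALSE]
    if (nrow(misc) && nrow(dose)) {
      rv <- misc$label == "Result_or_Value"
      clash <- vapply(seq_len(nrow(misc)), function(i) {
        rv[i] && any(misc$start[i] < dose$end & misc$end[i] > dose$start)
      }, logical(1))
      misc <- misc[!clash, , drop = FALSE]
    }
    doc <- add_entities(doc, misc)
  }
  cues <- empty_entities()
  if (isTRUE(config$negspec)) {
    cues <- detect_cues(doc, res$triggers)
    doc <- add_entities(doc, cues)
    cues <- doc$entities[doc$entities$layer == "cues", , drop = FALSE]
    scopes <- compute_scopes(doc, cues, res$triggers, config$max_window)
    umls_layer <- doc$entities[doc$entities$layer == "umls", , drop = FALSE]
    doc <- add_attributes(doc, assign_negspec(umls_layer, scopes))
  }
  if (isTRUE(config$attributes)) {
    umls_layer <- doc$entities[doc$entities$layer == "umls", , drop = FALSE]
    doc <- add_attributes(doc, assign_temporality(
      doc, umls_layer, res$attr_resources,
      future_heuristic = config$future_heuristic))
    doc <- add_attributes(doc, assign_experiencer(doc, umls_layer,
                                                  res$attr_resources))
    doc <- add_attributes(doc, assign_contraindicated(doc, umls_layer,
                                                      res$attr_resources))
    doc <- add_attributes(doc, assign_age_attr(umls_layer,
                                               res$attr_resources$age_terms))
  }
  doc
}

#' @rdname annotate
#' @export
run_pipeline <- annotate

#' Annotate a file or directory of files
#'
#' Processes every `.txt` under `input_path` (or the single file given),
#' writing one output per input with the same basename and the extension
#' of the chosen format, plus a summary log line per document (layer
#' counts) to stderr and optionally a log file.
#'
#' @param input_path a `.txt` file or a directory containing them.
#' @param out_dir output directory (created if needed).
#' @param config pipeline configuration.
#' @param lexicon,adapter passed to [annotate()].
#' @param format `"json"` or `"ann"` (default from config).
#' @param log_file optional path for the summary log.
#' @return Invisibly, a data.frame summary (file, status, layer counts);
#'   attribute `"n_failed"` carries the failure count.
#' @export
run_batch <- function(input_path, out_dir, config = default_config(),
                      lexicon = NULL, adapter = NULL, format = config$output,
                      log_file = NULL) {
  files <- if (length(input_path) == 1L && dir.exists(input_path)) {
    list.files(input_path, pattern = "\\.txt$", full.names = TRUE)
  } else input_path
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  logs <- character(0)
  rows <- list()
  n_failed <- 0L
  for (f in files) {
    status <- "ok"
    counts <- c(umls = 0L, temporal = 0L, medication = 0L, misc = 0L,
                cues = 0L, attributes = 0L)
    ok <- tryCatch({
      text <- paste(suppressWarnings(readLines(f, encoding = "UTF-8",
                                               warn = FALSE)),
                    collapse = "\n")
      doc <- annotate(text, config, lexicon, adapter,
                      doc_id = sub("\\.txt$", "", basename(f)))
      stem <- file.path(out_dir, sub("\\.txt$", "", basename(f)))
      if (format == "ann") write_brat(doc, stem)
      else doc_to_json(doc, paste0(stem, ".json"))
      for (lay in names(counts)[1:5]) {
        counts[lay] <- sum(doc$entities$layer == lay)
      }
      counts["attributes"] <- nrow(doc$attributes)
      TRUE
    }, error = function(e) {
      status <<- conditionMessage(e)
      FALSE
    })
    if (!ok) n_failed <- n_failed + 1L
    line <- sprintf("%s\t%s\t%s", basename(f),
                    if (ok) "ok" else "failed",
                    paste(sprintf("%s=%d", names(counts), counts),
                          collapse = " "))
    logs <- c(logs, line)
    message(line)
    rows[[length(rows) + 1L]] <- data.frame(
      file = basename(f), status = status, t(counts),
      stringsAsFactors = FALSE)
  }
  if (!is.null(log_file)) writeLines(logs, log_file)
  out <- do.call(rbind, rows)
  attr(out, "n_failed") <- n_failed
  invisible(out)
}
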