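# Dictionary-based entity recognition over a MedLexSp-style lexicon:
# entries carry a lemma, surface variants, semantic groups, UMLS CUIs and
# SNOMED CT codes; matching is greedy longest-match over token n-grams.

#' Fold a surface form into a lookup key
#'
#' Lowercases and (by default) strips Spanish accents (á é í ó ú ü; ñ is
#' kept, it is a distinct letter). Abbreviations are indexed unfolded and
#' matched case-sensitively, so `fold()` is only applied to ordinary forms.
#'
#' @param form character vector.
#' @param accent_fold strip accents (default TRUE).
#' @return folded character vector.
#' @export
fold <- function(form, accent_fold = TRUE) {
  out <- tolower(form)
  if (accent_fold) {
    out <- chartr("áéíóúü", "aeiouu", out)
  }
  out
}

# split a folded multiword form into its key (tokens joined by one space)
fold_key <- function(form, accent_fold = TRUE) {
  f <- fold(form, accent_fold)
  gsub("\\s+", " ", trimws(f))
}

split_pipe <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, "|", fixed = TRUE)[[1]])
}

#' Load a lexicon from a tab-separated file
#'
#' Expected UTF-8 TSV columns: `lemma`, `variants` (pipe-separated),
#' `groups` (pipe-separated semantic groups), `cuis`, `snomed`,
#' `is_abbrev`. Empty field means none. Rows sharing a (variant, group)
#' pair are merged with unioned codes.
#'
#' @param path path to the TSV file.
#' @param accent_fold fold accents when indexing (default TRUE).
#' @return An object of class `clin_lexicon`.
#' @export
load_lexicon <- function(path, accent_fold = TRUE) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(lines)) stop("empty lexicon file: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  required <- c("lemma", "variants", "groups", "cuis", "snomed", "is_abbrev")
  if (!identical(header, required)) {
    stop("lexicon format error at line 1: header must be ",
         paste(required, collapse = "\t"))
  }
  entries <- list()
  for (ln in seq_along(lines)[-1]) {
    if (!nzchar(trimws(lines[ln]))) next
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6L) {
      stop("lexicon format error at line ", ln, ": expected 6 columns, got ",
           length(f))
    }
    cuis <- split_pipe(f[4])
    bad <- cuis[!grepl("^C\\d{7}$", cuis)]
    if (length(bad)) {
      stop("lexicon format error at line ", ln, ": malformed CUI ",
           paste(bad, collapse = ", "))
    }
    variants <- unique(c(trimws(f[1]), split_pipe(f[2])))
    variants <- variants[nzchar(variants)]
    groups <- split_pipe(f[3])
    if (!length(variants)) stop("lexicon format error at line ", ln, ": no variants")
    if (!length(groups)) stop("lexicon format error at line ", ln, ": no groups")
    entries[[length(entries) + 1L]] <- list(
      lemma = trimws(f[1]), variants = variants, groups = groups,
      cuis = cuis, snomed = split_pipe(f[5]),
      is_abbrev = tolower(trimws(f[6])) %in% c("1", "true", "yes"))
  }
  build_lexicon(entries, accent_fold)
}

# Merge duplicate (variant, group) entries and build the indexes.
build_lexicon <- function(entries, accent_fold = TRUE) {
  # merge rule: rows sharing any (variant, group) pair are unioned
  merged <- list()
  seen <- new.env(parent = emptyenv())
  for (e in entries) {
    keys <- as.vector(outer(fold_key(e$variants, accent_fold), e$groups, paste))
    hit <- NA_integer_
    for (k in keys) {
      if (!is.null(seen[[k]])) { hit <- seen[[k]]; break }
    }
    if (is.na(hit)) {
      merged[[length(merged) + 1L]] <- e
      hit <- length(merged)
    } else {
      m <- merged[[hit]]
      m$variants <- unique(c(m$variants, e$variants))
      m$groups <- unique(c(m$groups, e$groups))
      m$cuis <- unique(c(m$cuis, e$cuis))
      m$snomed <- unique(c(m$snomed, e$snomed))
      merged[[hit]] <- m
    }
    for (k in as.vector(outer(fold_key(merged[[hit]]$variants, accent_fold),
                              merged[[hit]]$groups, paste))) {
      seen[[k]] <- hit
    }
  }
  index <- new.env(parent = emptyenv())
  abbrev_index <- new.env(parent = emptyenv())
  max_len <- 1L
  for (i in seq_along(merged)) {
    e <- merged[[i]]
    for (v in e$variants) {
      ntok <- length(strsplit(trimws(v), "\\s+")[[1]])
      max_len <- max(max_len, ntok)
      if (e$is_abbrev) {
        key <- gsub("\\s+", " ", trimws(v))
        abbrev_index[[key]] <- unique(c(abbrev_index[[key]], i))
      } else {
        key <- fold_key(v, accent_fold)
        index[[key]] <- unique(c(index[[key]], i))
      }
    }
  }
  structure(list(entries = merged, index = index,
                 abbrev_index = abbrev_index,
                 max_len = max_len, accent_fold = accent_fold),
            class = "clin_lexicon")
}

#' @export
print.clin_lexicon <- function(x, ...) {
  cat(sprintf("<clin_lexicon: %d entries, max variant length %d token(s)>\n",
              length(x$entries), x$max_len))
  invisible(x)
}

lookup_ids <- function(lexicon, surfaces, lemmas) {
  # surface path: abbreviation (case-sensitive, unfolded) then folded surface
  skey <- paste(surfaces, collapse = " ")
  ids <- lexicon$abbrev_index[[skey]]
  if (!is.null(ids)) return(list(ids = ids, via = "surface"))
  fkey <- paste(fold(surfaces, lexicon$accent_fold), collapse = " ")
  ids <- lexicon$index[[fkey]]
  if (!is.null(ids)) return(list(ids = ids, via = "surface"))
  # lemma path (ties at equal length lose to surface: tried second)
  lkey <- paste(fold(lemmas, lexicon$accent_fold), collapse = " ")
  ids <- lexicon$index[[lkey]]
  if (!is.null(ids)) return(list(ids = ids, via = "lemma"))
  NULL
}

entry_codes <- function(entry) {
  paste(c(if (length(entry$cuis)) paste0("UMLS:", entry$cuis),
          if (length(entry$snomed)) paste0("SNOMEDCT:", entry$snomed)),
        collapse = "|")
}

#' Dictionary entity matching
#'
#' Greedy left-to-right longest match over token n-grams within each
#' sentence (entities never cross sentence boundaries). At each position
#' the longest matching variant wins; surface forms are tried before lemma
#' sequences at the same length. Matched spans emit one entity per
#' matching semantic group (co-located entities when an entry belongs to
#' several groups); groups in `excluded_groups` are dropped, and when
#' `include_groups` is given only those groups are considered.
#'
#' @param doc a segmented [clin_document()].
#' @param lexicon a [load_lexicon()] result.
#' @param excluded_groups character vector of groups to suppress.
#' @param include_groups optional whitelist of groups to emit.
#' @return Entity data.frame (source `"dictionary"`, codes attached).
#' @export
match_entities <- function(doc, lexicon, excluded_groups = character(0),
                           include_groups = NULL) {
  if (!is_segmented(doc)) stop("document must be segmented before matching")
  wanted <- function(groups) {
    g <- setdiff(groups, excluded_groups)
    if (!is.null(include_groups)) g <- intersect(g, include_groups)
    g
  }
  out <- list()
  for (k in seq_len(nrow(doc$sentences))) {
    toks <- sentence_tokens(doc, k)
    n <- nrow(toks)
    i <- 1L
    while (i <= n) {
      hit <- NULL; hit_len <- 0L
      for (len in seq(min(lexicon$max_len, n - i + 1L), 1L)) {
        idx <- i:(i + len - 1L)
        res <- lookup_ids(lexicon, toks$surface[idx], toks$lemma[idx])
        if (!is.null(res)) {
          groups <- unique(unlist(lapply(lexicon$entries[res$ids], `[[`, "groups")))
          if (length(wanted(groups))) {
            hit <- res; hit_len <- len
            break
          }
        }
      }
      if (is.null(hit)) { i <- i + 1L; next }
      idx <- i:(i + hit_len - 1L)
      s <- toks$start[idx[1]]; e <- toks$end[idx[hit_len]]
      surf <- slice_text(doc$text, s, e)
      for (id in hit$ids) {
        entry <- lexicon$entries[[id]]
        for (g in wanted(entry$groups)) {
          out[[length(out) + 1L]] <- data.frame(
            label = g, start = s, end = e, surface = surf,
            codes = entry_codes(entry), stringsAsFactors = FALSE)
        }
      }
      i <- i + hit_len
    }
  }
  if (!length(out)) return(empty_entities())
  df <- unique(do.call(rbind, out))
  make_entities(df$label, df$start, df$end, df$surface,
                source = "dictionary", score = NA_real_, codes = df$codes)
}

#' Filter an entity's codes to one normalization scheme
#'
#' Looks the entity surface up in the lexicon (if it carries no codes yet)
#' and keeps only codes of the requested scheme. Unknown surfaces yield
#' empty codes and an otherwise unchanged entity.
#'
#' @param entity one-row entity data.frame.
#' @param lexicon a [load_lexicon()] result.
#' @param scheme `"UMLS"` or `"SNOMEDCT"`.
#' @return The entity row with `codes` filtered to the scheme.
#' @export
normalize_entity <- function(entity, lexicon, scheme = c("UMLS", "SNOMEDCT")) {
  if (length(scheme) != 1L || !scheme %in% c("UMLS", "SNOMEDCT")) {
    scheme <- match.arg(scheme)
  }
  codes <- split_pipe(entity$codes)
  if (!length(codes)) {
    surfaces <- strsplit(trimws(entity$surface), "\\s+")[[1]]
    res <- lookup_ids(lexicon, surfaces, tolower(surfaces))
    if (!is.null(res)) {
      codes <- unique(unlist(lapply(lexicon$entries[res$ids], function(e) {
        split_pipe(entry_codes(e))
      })))
    }
  }
  keep <- codes[startsWith(codes, paste0(scheme, ":"))]
  entity$codes <- paste(keep, collapse = "|")
  entity
}

# Apply normalize_entity over a whole entity table.
normalize_entities <- function(entities, lexicon, scheme) {
  if (!nrow(entities)) return(entities)
  for (i in seq_len(nrow(entities))) {
    entities[i, ] <- normalize_entity(entities[i, , drop = FALSE], lexicon, scheme)
  }
  entities
}
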