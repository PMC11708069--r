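# Shared machinery for the rule-based taggers: packaged resource loading,
# regex scanning with code-point offsets, and a small Spanish number-word
# grammar used by the temporal and dose patterns.

.res_cache <- new.env(parent = emptyenv())

res_path <- function(file) {
  p <- system.file("extdata", file, package = "clinspan")
  if (!nzchar(p)) stop("packaged resource not found: ", file)
  p
}

read_lines_utf8 <- function(path) {
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read a one-entry-per-line term list
#' @param path file path (UTF-8, `#` comments allowed).
#' @return character vector of terms.
#' @export
read_term_list <- function(path) read_lines_utf8(path)

# Spanish number words up to the nineties, including "y" compounds
# ("treinta y cinco"); needed so "dos horas" parses like "2 horas".
number_word_pattern <- function() {
  units <- c("un", "uno", "una", "dos", "tres", "cuatro", "cinco", "seis",
             "siete", "ocho", "nueve")
  teens <- c("diez", "once", "doce", "trece", "catorce", "quince",
             "dieciséis", "dieciseis", "diecisiete", "dieciocho", "diecinueve",
             "veinte", "veintiún", "veintiun", "veintiuno", "veintidós",
             "veintidos", "veintitrés", "veintitres", "veinticuatro",
             "veinticinco", "veintiséis", "veintiseis", "veintisiete",
             "veintiocho", "veintinueve")
  tens <- c("treinta", "cuarenta", "cincuenta", "sesenta", "setenta",
            "ochenta", "noventa")
  paste0("(?:(?:", paste(tens, collapse = "|"), ")(?:\\s+y\\s+(?:",
         paste(units, collapse = "|"), "))?|",
         paste(teens, collapse = "|"), "|",
         paste(units, collapse = "|"), ")")
}

# number token: digits (decimal comma/dot) or a number word
number_pattern <- function() {
  paste0("(?:\\d+(?:[.,]\\d+)?|", number_word_pattern(), ")")
}

# wrap a pattern with boundaries that respect accented letters
bounded <- function(pattern) {
  paste0("(?<![\\p{L}\\p{N}])(?:", pattern, ")(?![\\p{L}\\p{N}])")
}

# Find all matches of a perl regex in `text`; returns 0-based code-point
# spans. If the pattern has a capture group 1, the span is the group's.
re_find <- function(text, pattern, ignore_case = TRUE) {
  m <- gregexpr(pattern, text, perl = TRUE, ignore.case = ignore_case)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  start <- m - 1L
  end <- start + attr(m, "match.length")
  cs <- attr(m, "capture.start")
  if (!is.null(cs) && ncol(cs) >= 1L) {
    cl <- attr(m, "capture.length")
    has_grp <- cs[, 1] > 0L
    start[has_grp] <- cs[has_grp, 1] - 1L
    end[has_grp] <- start[has_grp] + cl[has_grp, 1]
  }
  data.frame(start = start, end = end, stringsAsFactors = FALSE)
}

# index of the token containing (or first token at/after) a char offset
token_at <- function(toks, offset) {
  hit <- which(toks$start <= offset & toks$end > offset)
  if (length(hit)) hit[1] else NA_integer_
}

# index range of tokens fully covered by [start, end)
tokens_in_span <- function(toks, start, end) {
  which(toks$start >= start & toks$end <= end)
}

#' Resolve overlapping candidate spans
#'
#' Keeps a non-overlapping subset, preferring higher priority, then longer
#' span, then smaller start offset.
#'
#' @param matches data.frame with columns `start`, `end`, `priority` (and
#'   any payload columns, preserved).
#' @return The kept rows, ordered by start.
#' @export
resolve_overlaps <- function(matches) {
  if (!nrow(matches)) return(matches)
  ord <- order(-matches$priority, -(matches$end - matches$start), matches$start)
  m <- matches[ord, , drop = FALSE]
  kept <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    ok <- TRUE
    for (j in which(kept)) {
      if (m$start[i] < m$end[j] && m$end[i] > m$start[j]) { ok <- FALSE; break }
    }
    kept[i] <- ok
  }
  out <- m[kept, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}
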