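# Entity-level scoring: strict (exact span + class) and relaxed
# (any-overlap + same class, one-to-one greedy pairing), micro-averaged
# precision/recall/F1, pairwise inter-annotator agreement F-measure, and
# corpus statistics.

#' Strict entity comparison
#'
#' A true positive requires identical (start, end, label); remaining
#' predictions are false positives, remaining gold entities false
#' negatives. Counts are per label.
#'
#' @param gold,pred entity data.frames over the same document text.
#' @return data.frame with columns `label`, `tp`, `fp`, `fn`
#'   (a MatchCounts table).
#' @export
compare_strict <- function(gold, pred) {
  key <- function(df) paste(df$start, df$end, df$label)
  gk <- key(gold); pk <- key(pred)
  labels <- sort(unique(c(gold$label, pred$label)))
  res <- lapply(labels, function(l) {
    g <- gk[gold$label == l]; p <- pk[pred$label == l]
    tp <- length(intersect_multiset(g, p))
    data.frame(label = l, tp = tp, fp = length(p) - tp, fn = length(g) - tp,
               stringsAsFactors = FALSE)
  })
  if (!length(res)) {
    return(data.frame(label = character(), tp = integer(), fp = integer(),
                      fn = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, res)
}

intersect_multiset <- function(a, b) {
  out <- character(0)
  b_left <- b
  for (x in a) {
    i <- match(x, b_left)
    if (!is.na(i)) { out <- c(out, x); b_left <- b_left[-i] }
  }
  out
}

#' Relaxed entity comparison
#'
#' A true positive requires the same label and at least one character of
#' overlap, with one-to-one greedy matching by descending overlap length
#' (ties: smaller gold start). Unmatched predictions/gold count as FP/FN.
#'
#' @inheritParams compare_strict
#' @return MatchCounts data.frame.
#' @export
compare_relaxed <- function(gold, pred) {
  labels <- sort(unique(c(gold$label, pred$label)))
  res <- lapply(labels, function(l) {
    g <- gold[gold$label == l, , drop = FALSE]
    p <- pred[pred$label == l, , drop = FALSE]
    pairs <- list()
    for (i in seq_len(nrow(g))) {
      for (j in seq_len(nrow(p))) {
        ov <- min(g$end[i], p$end[j]) - max(g$start[i], p$start[j])
        if (ov > 0L) {
          pairs[[length(pairs) + 1L]] <- c(i = i, j = j, ov = ov,
                                           gs = g$start[i])
        }
      }
    }
    tp <- 0L
    if (length(pairs)) {
      pm <- do.call(rbind, pairs)
      pm <- pm[order(-pm[, "ov"], pm[, "gs"]), , drop = FALSE]
      used_g <- logical(nrow(g)); used_p <- logical(nrow(p))
      for (r in seq_len(nrow(pm))) {
        i <- pm[r, "i"]; j <- pm[r, "j"]
        if (!used_g[i] && !used_p[j]) {
          used_g[i] <- TRUE; used_p[j] <- TRUE; tp <- tp + 1L
        }
      }
    }
    data.frame(label = l, tp = tp, fp = nrow(p) - tp, fn = nrow(g) - tp,
               stringsAsFactors = FALSE)
  })
  if (!length(res)) {
    return(data.frame(label = character(), tp = integer(), fp = integer(),
                      fn = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, res)
}

#' Precision, recall and F1 from match counts
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`, `F1 = 2PR / (P + R)`;
#' all-zero counts yield (0, 0, 0) by convention.
#'
#' @param counts a MatchCounts data.frame (summed over labels) or a list/
#'   vector with elements `tp`, `fp`, `fn`.
#' @return list with elements `P`, `R`, `F1`.
#' @export
prf <- function(counts) {
  if (is.data.frame(counts)) {
    tp <- sum(counts$tp); fp <- sum(counts$fp); fn <- sum(counts$fn)
  } else {
    tp <- counts[["tp"]]; fp <- counts[["fp"]]; fn <- counts[["fn"]]
  }
  if (any(c(tp, fp, fn) < 0)) stop("negative counts")
  P <- if (tp + fp > 0) tp / (tp + fp) else 0
  R <- if (tp + fn > 0) tp / (tp + fn) else 0
  F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  list(P = P, R = R, F1 = F1)
}

#' Micro-averaged metrics
#'
#' [prf()] over TP/FP/FN summed across labels (appropriate under class
#' imbalance).
#'
#' @param counts a per-label MatchCounts data.frame.
#' @return list with elements `P`, `R`, `F1`.
#' @export
micro_average <- function(counts) prf(counts)

#' Per-label metric table
#' @param counts MatchCounts data.frame.
#' @return data.frame with label, tp, fp, fn, P, R, F1.
#' @export
per_label_metrics <- function(counts) {
  if (!nrow(counts)) {
    return(cbind(counts, P = numeric(0), R = numeric(0), F1 = numeric(0)))
  }
  m <- t(vapply(seq_len(nrow(counts)), function(i) {
    unlist(prf(counts[i, , drop = FALSE]))
  }, numeric(3)))
  cbind(counts, as.data.frame(m))
}

#' Inter-annotator agreement F-measure
#'
#' Pairwise F-measure between two annotators' entity sets (one arbitrarily
#' treated as reference); F1 is symmetric under argument swap.
#'
#' @param setA,setB entity data.frames over the same document.
#' @param criterion `"strict"` or `"relaxed"`.
#' @return list with elements `P`, `R`, `F1`.
#' @export
iaa_fmeasure <- function(setA, setB, criterion = c("strict", "relaxed")) {
  criterion <- match.arg(criterion)
  cmp <- if (criterion == "strict") compare_strict else compare_relaxed
  micro_average(cmp(setA, setB))
}

#' Corpus statistics
#'
#' Totals and per-document means of entities and attributes. Means are
#' reported to two decimals (floored), via [mean_per_text()].
#'
#' @param docs list of [clin_document()] objects.
#' @return list with totals and means.
#' @export
corpus_stats <- function(docs) {
  n <- length(docs)
  total_entities <- sum(vapply(docs, function(d) nrow(d$entities), integer(1)))
  total_attributes <- sum(vapply(docs, function(d) nrow(d$attributes), integer(1)))
  if (n == 0L) {
    warning("empty corpus: means undefined, reported as 0")
    return(list(n_docs = 0L, total_entities = 0L, total_attributes = 0L,
                mean_entities = 0, mean_attributes = 0))
  }
  list(n_docs = n,
       total_entities = total_entities,
       total_attributes = total_attributes,
       mean_entities = mean_per_text(total_entities, n),
       mean_attributes = mean_per_text(total_attributes, n))
}

#' Per-text mean, floored at two decimals
#'
#' The reporting convention for corpus averages: `floor(100 * total / n)
#' / 100` (86389 entities over 1200 texts -> 71.99).
#'
#' @param total total count.
#' @param n_texts number of documents.
#' @return numeric scalar.
#' @export
mean_per_text <- function(total, n_texts) {
  if (n_texts <= 0) return(0)
  floor(100 * total / n_texts) / 100
}
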