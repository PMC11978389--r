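# Span-matching evaluation in the SemEval-2013 Task 9.1 style (strict and
# partial modes), precision/recall/F1, two-system overlap accounting against
# one gold set, and Cohen's kappa for inter-annotator agreement.

#' Match predicted mentions against gold spans
#'
#' Strict mode: a predicted mention is a true positive iff a gold mention has
#' the identical (entity type, document, block, start, end). Partial mode: a
#' true positive needs at least one character of overlap with a gold mention
#' of the same type in the same block. Each gold mention can absorb at most
#' one prediction; predictions are matched greedily in positional order.
#' Offsets are the block-relative ones (`block_start`, `block_end`).
#'
#' @param gold,predicted mention data.frames over the same corpus.
#' @param mode `"strict"` or `"partial"`.
#' @return data.frame with one row per entity type present in either set:
#'   `entity_type`, `mode`, `tp`, `fp`, `fn`.
#' @export
match_mentions <- function(gold, predicted, mode = c("strict", "partial")) {
  mode <- match.arg(mode)
  if (nrow(gold)) check_mentions(gold, "gold")
  if (nrow(predicted)) check_mentions(predicted, "predicted")
  types <- sort(unique(c(gold$entity_type, predicted$entity_type)))
  out <- lapply(types, function(tt) {
    g <- gold[gold$entity_type == tt, , drop = FALSE]
    p <- predicted[predicted$entity_type == tt, , drop = FALSE]
    p <- p[order(p$doc_id, p$block_index, p$block_start, p$block_end), , drop = FALSE]
    g <- g[order(g$doc_id, g$block_index, g$block_start, g$block_end), , drop = FALSE]
    gold_used <- logical(nrow(g))
    tp <- 0L
    gblk <- paste(g$doc_id, g$block_index)
    for (i in seq_len(nrow(p))) {
      pblk <- paste(p$doc_id[i], p$block_index[i])
      cand <- if (mode == "strict") {
        which(!gold_used & gblk == pblk &
                g$block_start == p$block_start[i] & g$block_end == p$block_end[i])
      } else {
        which(!gold_used & gblk == pblk &
                g$block_start < p$block_end[i] & g$block_end > p$block_start[i])
      }
      if (length(cand)) {
        gold_used[cand[1L]] <- TRUE
        tp <- tp + 1L
      }
    }
    data.frame(entity_type = tt, mode = mode, tp = tp,
               fp = nrow(p) - tp, fn = nrow(g) - tp, stringsAsFactors = FALSE)
  })
  if (!length(out)) {
    return(data.frame(entity_type = character(), mode = character(),
                      tp = integer(), fp = integer(), fn = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Precision / recall / F1 from match counts
#'
#' `P = tp/(tp+fp)`, `R = tp/(tp+fn)`, `F1 = 2PR/(P+R)`; each is 0 when its
#' denominator is 0. Rounded columns (2 decimals, half away from zero) are
#' reported alongside the exact values.
#'
#' @param counts output of [match_mentions()].
#' @return `counts` with added columns `precision`, `recall`, `f1` and their
#'   `_2dp` rounded counterparts.
#' @export
score <- function(counts) {
  p <- ifelse(counts$tp + counts$fp > 0, counts$tp / (counts$tp + counts$fp), 0)
  r <- ifelse(counts$tp + counts$fn > 0, counts$tp / (counts$tp + counts$fn), 0)
  f <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  counts$precision <- p
  counts$recall <- r
  counts$f1 <- f
  counts$precision_2dp <- round_half_away(p, 2)
  counts$recall_2dp <- round_half_away(r, 2)
  counts$f1_2dp <- round_half_away(f, 2)
  counts
}

#' F1 from (possibly already rounded) precision and recall
#'
#' Harmonic mean `2PR/(P+R)` rounded half away from zero to `digits`
#' decimals; 0 when `P + R = 0`. This is the arithmetic used to recompute
#' published benchmark table cells from their printed precision and recall.
#'
#' @param precision,recall numeric vectors in \[0, 1\].
#' @param digits decimals for rounding (default 2, matching benchmark
#'   tables; use `Inf` for the exact value).
#' @return numeric vector of F1 scores.
#' @export
f1_from_pr <- function(precision, recall, digits = 2) {
  f <- ifelse(precision + recall > 0,
              2 * precision * recall / (precision + recall), 0)
  if (is.finite(digits)) f <- round_half_away(f, digits) else f
}

#' Two-system overlap accounting against one gold set
#'
#' For each system and entity type: `shared` = strict true positives against
#' gold, `system_only` = strict false positives, `gold_only` = strict false
#' negatives. `gold_only + shared` equals the gold count for every system.
#'
#' @param gold gold mention set.
#' @param system_a,system_b predicted mention sets.
#' @param names length-2 character, display names of the systems.
#' @return data.frame with columns `system`, `entity_type`, `shared`,
#'   `system_only`, `gold_only`.
#' @export
overlap_report <- function(gold, system_a, system_b,
                           names = c("system_a", "system_b")) {
  one <- function(sys, nm) {
    m <- match_mentions(gold, sys, mode = "strict")
    data.frame(system = nm, entity_type = m$entity_type, shared = m$tp,
               system_only = m$fp, gold_only = m$fn, stringsAsFactors = FALSE)
  }
  rbind(one(system_a, names[1]), one(system_b, names[2]))
}

#' Cohen's kappa for two annotators
#'
#' Observed agreement `p_o` is the fraction of positions with equal labels;
#' expected agreement `p_e = sum_c freq_a(c) * freq_b(c)` over categories;
#' `kappa = (p_o - p_e) / (1 - p_e)`. When `p_e = 1` (both annotators
#' constant on the same label) kappa is undefined and reported as 1 with
#' `undefined = TRUE`.
#'
#' @param labels_a,labels_b equal-length category label vectors.
#' @return list with `p_o`, `p_e`, `kappa`, `undefined`.
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    validation_error("label sequences differ in length: ",
                     length(labels_a), " vs ", length(labels_b))
  }
  if (!length(labels_a)) validation_error("label sequences must be non-empty")
  labels_a <- as.character(labels_a)
  labels_b <- as.character(labels_b)
  n <- length(labels_a)
  p_o <- mean(labels_a == labels_b)
  cats <- union(labels_a, labels_b)
  fa <- vapply(cats, function(c) mean(labels_a == c), 0)
  fb <- vapply(cats, function(c) mean(labels_b == c), 0)
  p_e <- sum(fa * fb)
  if (p_e >= 1) {
    return(list(p_o = p_o, p_e = p_e, kappa = 1, undefined = TRUE))
  }
  list(p_o = p_o, p_e = p_e, kappa = (p_o - p_e) / (1 - p_e), undefined = FALSE)
}
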