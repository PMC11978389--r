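# Same-sentence co-occurrence extraction, aggregation into unique
# associations, and ranking. Two mapped mentions of different groundable
# types (GP, DS, CD) in one sentence form one piece of association evidence;
# same-type pairs and organism mentions are never paired. Cross-sentence
# relations (coreference, inferred context) are deliberately not captured.

ASSOCIATION_KINDS <- c("GP-DS", "GP-CD", "DS-CD")

# canonical kind string for two entity types (order GP < DS < CD)
pair_kind <- function(type_1, type_2) {
  r1 <- TYPE_ORDER[type_1]; r2 <- TYPE_ORDER[type_2]
  lo <- ifelse(r1 <= r2, type_1, type_2)
  hi <- ifelse(r1 <= r2, type_2, type_1)
  paste0(lo, "-", hi)
}

#' Extract same-sentence co-occurrences
#'
#' One co-occurrence per unordered pair of mapped mentions in the same
#' sentence whose entity types form an allowed kind (GP-DS, GP-CD, DS-CD).
#' Pairs of the same type, pairs involving OG, pairs sharing a span, and
#' pairs where both endpoints ground to the same identifier are excluded.
#' Endpoints are canonicalized: entity-type order GP < DS < CD, then
#' identifier order.
#'
#' @param groundings grounding data.frame ([ground_corpus()] output
#'   `$groundings`; UNMAPPED rows are ignored).
#' @param sentences optional sentence table; when given, each co-occurrence
#'   carries its sentence string as `evidence_text`.
#' @return data.frame with columns `doc_id`, `block_index`, `sent_index`,
#'   `kind`, `entry_id_1`, `entry_id_2`, `evidence_text`.
#' @export
extract_cooccurrences <- function(groundings, sentences = NULL) {
  empty <- data.frame(doc_id = character(), block_index = integer(),
                      sent_index = integer(), kind = character(),
                      entry_id_1 = character(), entry_id_2 = character(),
                      evidence_text = character(), stringsAsFactors = FALSE)
  if (!nrow(groundings)) return(empty)
  m <- groundings[groundings$entity_type %in% GROUNDABLE_TYPES &
                    groundings$entry_id != "UNMAPPED" &
                    !is.na(groundings$sent_index), , drop = FALSE]
  if (!nrow(m)) return(empty)
  stext <- NULL
  if (!is.null(sentences)) {
    skey <- paste(sentences$doc_id, sentences$block_index, sentences$sent_index)
    stext <- function(doc, blk, sent) {
      i <- match(paste(doc, blk, sent), skey)
      if (is.na(i)) NA_character_ else sentences$text[i]
    }
  }
  groups <- split(seq_len(nrow(m)),
                  paste(m$doc_id, m$block_index, m$sent_index, sep = "\r"))
  out <- list()
  for (ix in groups) {
    if (length(ix) < 2L) next
    ev <- if (!is.null(stext)) {
      stext(m$doc_id[ix[1]], m$block_index[ix[1]], m$sent_index[ix[1]])
    } else NA_character_
    for (a in seq_along(ix)[-length(ix)]) {
      for (b in seq((a + 1), length(ix))) {
        i <- ix[a]; j <- ix[b]
        if (m$entity_type[i] == m$entity_type[j]) next
        if (m$entry_id[i] == m$entry_id[j]) next
        if (m$char_start[i] == m$char_start[j] && m$char_end[i] == m$char_end[j]) next
        swap <- TYPE_ORDER[m$entity_type[i]] > TYPE_ORDER[m$entity_type[j]]
        p <- if (swap) c(j, i) else c(i, j)
        out[[length(out) + 1L]] <- data.frame(
          doc_id = m$doc_id[i], block_index = m$block_index[i],
          sent_index = m$sent_index[i],
          kind = pair_kind(m$entity_type[i], m$entity_type[j]),
          entry_id_1 = m$entry_id[p[1]], entry_id_2 = m$entry_id[p[2]],
          evidence_text = ev, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate co-occurrences into unique association records
#'
#' Groups by canonical (kind, identifier pair). `evidence_count` counts
#' sentence-level co-occurrences; `document_count` counts distinct documents.
#' The evidence counts always sum to the number of input co-occurrences.
#'
#' @param cooccurrences output of [extract_cooccurrences()].
#' @return data.frame `kind`, `entry_id_1`, `entry_id_2`, `evidence_count`,
#'   `document_count`.
#' @export
aggregate_associations <- function(cooccurrences) {
  if (!nrow(cooccurrences)) {
    return(data.frame(kind = character(), entry_id_1 = character(),
                      entry_id_2 = character(), evidence_count = integer(),
                      document_count = integer(), stringsAsFactors = FALSE))
  }
  key <- paste(cooccurrences$kind, cooccurrences$entry_id_1,
               cooccurrences$entry_id_2, sep = "\r")
  first <- !duplicated(key)
  rec <- cooccurrences[first, c("kind", "entry_id_1", "entry_id_2"), drop = FALSE]
  rec$evidence_count <- as.integer(table(key)[paste(rec$kind, rec$entry_id_1,
                                                    rec$entry_id_2, sep = "\r")])
  rec$document_count <- vapply(seq_len(nrow(rec)), function(i) {
    k <- paste(rec$kind[i], rec$entry_id_1[i], rec$entry_id_2[i], sep = "\r")
    length(unique(cooccurrences$doc_id[key == k]))
  }, 0L)
  rec <- rec[order(match(rec$kind, ASSOCIATION_KINDS), rec$entry_id_1, rec$entry_id_2), ,
             drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Score and rank association records
#'
#' The relevance score is `log10(1 + evidence_count) * max(0, cos)` where
#' `cos` is the cosine similarity between the preferred-label phrase vectors
#' of the two endpoints. When either phrase vector is unavailable the score
#' is 0 and flagged (`score_defined = FALSE`). Records are sorted by
#' descending score within each kind, ties broken by canonical identifier
#' order. The formula is a package convention, isolated here so it can be
#' swapped out.
#'
#' @param records output of [aggregate_associations()].
#' @param model a `litmine_embeddings` trained on the same corpus.
#' @param lexicons named list of lexicons (by entity type) supplying
#'   preferred labels.
#' @return `records` with `score` and `score_defined` columns, sorted.
#' @export
rank_associations <- function(records, model, lexicons) {
  if (inherits(lexicons, "litmine_lexicon")) lexicons <- list(lexicons)
  if (is.null(names(lexicons)) || any(!nzchar(names(lexicons)))) {
    names(lexicons) <- vapply(lexicons, function(l) l$entity_type, "")
  }
  label_of <- function(id) {
    for (lex in lexicons) {
      hit <- match(id, lex$entries$entry_id)
      if (!is.na(hit)) return(lex$entries$preferred_label[hit])
    }
    NA_character_
  }
  records$score <- 0
  records$score_defined <- FALSE
  for (i in seq_len(nrow(records))) {
    l1 <- label_of(records$entry_id_1[i])
    l2 <- label_of(records$entry_id_2[i])
    v1 <- if (!is.na(l1)) phrase_vector(model, l1) else NULL
    v2 <- if (!is.na(l2)) phrase_vector(model, l2) else NULL
    if (is.null(v1) || is.null(v2)) next
    records$score[i] <- log10(1 + records$evidence_count[i]) *
      max(0, cosine_similarity(v1, v2))
    records$score_defined[i] <- TRUE
  }
  ord <- order(match(records$kind, ASSOCIATION_KINDS), -records$score,
               records$entry_id_1, records$entry_id_2)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  records
}

#' Write association records as TSV
#' @param records association data.frame.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_associations <- function(records, path) {
  cols <- intersect(c("kind", "entry_id_1", "entry_id_2", "evidence_count",
                      "document_count", "score", "score_defined"), names(records))
  utils::write.table(records[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
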