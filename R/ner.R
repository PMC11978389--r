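# Dictionary / gazetteer entity tagger — the baseline system.
#
# Matching policy:
#  * ordinary lexicon terms are matched case-insensitively via their
#    normalized form; short all-uppercase terms (gene-symbol style) are
#    matched case-sensitively only, so "WAS deficiency" hits the WAS gene
#    while "the sample was tested" does not;
#  * matches must respect token boundaries: a hit may not start or end
#    inside an alphanumeric run (hyphens count as boundaries);
#  * within an entity type, overlapping candidates are resolved
#    longest-match-first, ties by leftmost start; contained candidates are
#    dropped. Overlaps across entity types are permitted.
#  * blacklisted terms (case-insensitive) are excluded at compile time;
#    case-sensitively indexed short terms are exempt, since the case
#    requirement already disambiguates them from common words.

#' Compile a multi-lexicon matcher
#'
#' @param lexicons a single `litmine_lexicon` or a list of them; entity
#'   types may repeat across lexicons.
#' @param blacklist a `litmine_blacklist` (default empty).
#' @return object of class `litmine_matcher`.
#' @export
compile_matcher <- function(lexicons, blacklist = load_blacklist()) {
  if (inherits(lexicons, "litmine_lexicon")) lexicons <- list(lexicons)
  if (!length(lexicons)) validation_error("compile_matcher needs at least one lexicon")
  rows <- list()
  for (lex in lexicons) {
    if (!inherits(lex, "litmine_lexicon")) validation_error("not a lexicon object")
    # case-insensitive patterns: every normalized index term not blacklisted
    ci_terms <- ls(lex$term_index)
    cs_terms <- ls(lex$cs_index)
    # terms living only in the case-sensitive index: all-caps short forms
    cs_norm <- unique(normalize_term(cs_terms))
    ci_terms <- setdiff(ci_terms, cs_norm)
    ci_terms <- ci_terms[!blacklist_contains(blacklist, ci_terms)]
    if (length(ci_terms)) {
      rows[[length(rows) + 1L]] <- data.frame(
        pattern = ci_terms, case_sensitive = FALSE,
        entity_type = lex$entity_type,
        ids = I(lapply(ci_terms, function(t) lex$term_index[[t]])),
        stringsAsFactors = FALSE
      )
    }
    if (length(cs_terms)) {
      rows[[length(rows) + 1L]] <- data.frame(
        pattern = cs_terms, case_sensitive = TRUE,
        entity_type = lex$entity_type,
        ids = I(lapply(cs_terms, function(t) lex$cs_index[[t]])),
        stringsAsFactors = FALSE
      )
    }
  }
  pat <- do.call(rbind, rows)
  if (is.null(pat) || !nrow(pat)) validation_error("matcher has no patterns after filtering")
  # merge duplicate (pattern, case, type) rows across lexicons
  key <- paste(pat$pattern, pat$case_sensitive, pat$entity_type, sep = "\r")
  if (anyDuplicated(key)) {
    ids <- tapply(seq_len(nrow(pat)), key, function(ix) {
      sort(unique(unlist(pat$ids[ix])))
    })
    first <- !duplicated(key)
    pat <- pat[first, , drop = FALSE]
    pat$ids <- I(unname(ids[paste(pat$pattern, pat$case_sensitive, pat$entity_type, sep = "\r")]))
  }
  pat$nchar <- nchar(pat$pattern)
  pat <- pat[order(pat$entity_type, -pat$nchar, pat$pattern), , drop = FALSE]
  rownames(pat) <- NULL
  structure(list(patterns = pat, blacklist = blacklist), class = "litmine_matcher")
}

#' @export
print.litmine_matcher <- function(x, ...) {
  cat(sprintf("<litmine_matcher patterns=%d types=%s>\n", nrow(x$patterns),
              paste(sort(unique(x$patterns$entity_type)), collapse = ",")))
  invisible(x)
}

# boundary check: positions are 0-based half-open within `text`
is_token_bounded <- function(text, start, end) {
  before <- if (start > 0) substr(text, start, start) else ""
  after <- if (end < nchar(text)) substr(text, end + 1L, end + 1L) else ""
  !grepl("[[:alnum:]]", before) && !grepl("[[:alnum:]]", after)
}

# raw candidate hits for a set of sentences; returns data.frame with
# sentence row index, entity_type, char_start/char_end (0-based), candidate ids
match_candidates <- function(matcher, texts) {
  lower <- stringi::stri_trans_tolower(texts)
  pat <- matcher$patterns
  hits <- list()
  for (p in seq_len(nrow(pat))) {
    hay <- if (pat$case_sensitive[p]) texts else lower
    locs <- stringi::stri_locate_all_fixed(hay, pat$pattern[p])
    for (srow in seq_along(locs)) {
      loc <- locs[[srow]]
      if (all(is.na(loc[, 1]))) next
      for (k in seq_len(nrow(loc))) {
        s0 <- loc[k, 1] - 1L   # 0-based start
        e0 <- loc[k, 2]        # half-open end
        if (!is_token_bounded(texts[srow], s0, e0)) next
        hits[[length(hits) + 1L]] <- data.frame(
          srow = srow, entity_type = pat$entity_type[p],
          char_start = s0, char_end = e0,
          ids = I(list(pat$ids[[p]])), stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(srow = integer(), entity_type = character(),
                      char_start = integer(), char_end = integer(),
                      ids = I(list()), stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

# longest-then-leftmost greedy overlap resolution within one (sentence, type)
resolve_overlaps <- function(cand) {
  if (nrow(cand) <= 1L) return(cand)
  len <- cand$char_end - cand$char_start
  ord <- order(-len, cand$char_start)
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  taken_s <- integer(0); taken_e <- integer(0)
  for (i in seq_len(nrow(cand))) {
    s <- cand$char_start[i]; e <- cand$char_end[i]
    if (!any(s < taken_e & e > taken_s)) {
      keep[i] <- TRUE
      taken_s <- c(taken_s, s); taken_e <- c(taken_e, e)
    }
  }
  cand[keep, , drop = FALSE]
}

#' Tag one sentence
#'
#' @param matcher a `litmine_matcher`.
#' @param sentence either a sentence text string or a one-row sentence
#'   data.frame from [split_sentences()].
#' @return mention data.frame (sentence-relative offsets; block offsets
#'   filled when a sentence row is supplied).
#' @export
tag_sentence <- function(matcher, sentence) {
  if (is.character(sentence)) {
    sentence <- data.frame(doc_id = "doc", block_index = 0L, sent_index = 0L,
                           char_start = 0L, char_end = nchar(sentence),
                           text = sentence, stringsAsFactors = FALSE)
  }
  tag_sentences(matcher, sentence)
}

# shared implementation over a sentence table
tag_sentences <- function(matcher, sentences) {
  if (!nrow(sentences)) return(empty_mentions())
  cand <- match_candidates(matcher, sentences$text)
  if (!nrow(cand)) return(empty_mentions())
  parts <- split(cand, list(cand$srow, cand$entity_type), drop = TRUE)
  res <- do.call(rbind, lapply(parts, resolve_overlaps))
  res <- res[order(res$srow, res$char_start, res$entity_type), , drop = FALSE]
  out <- data.frame(
    doc_id = sentences$doc_id[res$srow],
    block_index = sentences$block_index[res$srow],
    sent_index = sentences$sent_index[res$srow],
    entity_type = res$entity_type,
    char_start = res$char_start, char_end = res$char_end,
    block_start = sentences$char_start[res$srow] + res$char_start,
    block_end = sentences$char_start[res$srow] + res$char_end,
    surface = slice_chars(sentences$text[res$srow], res$char_start, res$char_end),
    source = "dictionary", score = NA_real_, stringsAsFactors = FALSE
  )
  out$candidate_ids <- res$ids
  rownames(out) <- NULL
  out
}

#' Tag a whole corpus
#'
#' Equivalent to concatenating [tag_sentence()] over every sentence, in
#' corpus order (document, block, sentence, start offset).
#'
#' @param matcher a `litmine_matcher`.
#' @param corpus corpus data.frame, or an already-split sentence table (must
#'   then carry a `text` column plus sentence locators).
#' @param abbreviations splitter abbreviation list (used when `corpus` is a
#'   block table).
#' @return mention data.frame with both sentence- and block-relative offsets
#'   and a `candidate_ids` list-column of lexicon entry ids per mention.
#' @export
tag_corpus <- function(matcher, corpus, abbreviations = default_abbreviations()) {
  sentences <- if ("sent_index" %in% names(corpus) && "text" %in% names(corpus) &&
                   "char_start" %in% names(corpus)) {
    corpus
  } else {
    split_sentences(corpus, abbreviations)
  }
  # tag_sentences already emits mentions in sentence-table (corpus) order
  tag_sentences(matcher, sentences)
}
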