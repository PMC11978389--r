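# Fixtures built in code. Offsets are 0-based half-open characters.

# one-block corpus from bare texts
make_corpus <- function(texts, kind = "paragraph", doc_ids = NULL) {
  doc_ids <- doc_ids %||% sprintf("d%d", seq_along(texts))
  data.frame(doc_id = doc_ids, block_index = 0L, kind = kind, text = texts,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny typed lexicon from label -> id pairs; synonyms as "a|b"
make_lexicon <- function(entity_type, ..., name = paste0("toy-", entity_type)) {
  rows <- list(...)
  entries <- data.frame(
    entry_id = vapply(rows, `[[`, "", "id"),
    preferred_label = vapply(rows, `[[`, "", "label"),
    synonyms = vapply(rows, function(r) r$synonyms %||% "", ""),
    stringsAsFactors = FALSE
  )
  as_lexicon(entries, entity_type, name)
}

entry <- function(id, label, synonyms = NULL) {
  list(id = id, label = label, synonyms = synonyms)
}

# mention row with block-level offsets over a one-block corpus
make_mention <- function(doc_id, type, start, end, surface,
                         block_index = 0L, sent_index = 0L) {
  data.frame(doc_id = doc_id, block_index = block_index,
             sent_index = sent_index, entity_type = type,
             char_start = start, char_end = end,
             block_start = start, block_end = end, surface = surface,
             source = "gold", score = NA_real_, stringsAsFactors = FALSE)
}

bind_mentions <- function(...) do.call(rbind, list(...))

# blacklist object from a character vector (no file)
make_blacklist <- function(terms) {
  f <- withr::local_tempfile(lines = terms, .local_envir = parent.frame())
  load_blacklist(f)
}

# random mention set over `n_blocks` blocks of length `len`, for oracle tests
random_mentions <- function(n, types = c("GP", "DS"), n_docs = 2, len = 60) {
  if (n == 0) {
    m <- make_mention("d1", "GP", 0L, 1L, "x")
    return(m[0, ])
  }
  starts <- sample(0:(len - 6), n, replace = TRUE)
  widths <- sample(2:5, n, replace = TRUE)
  data.frame(
    doc_id = sample(sprintf("d%d", seq_len(n_docs)), n, replace = TRUE),
    block_index = 0L, sent_index = 0L,
    entity_type = sample(types, n, replace = TRUE),
    char_start = starts, char_end = starts + widths,
    block_start = starts, block_end = starts + widths,
    surface = strrep("x", widths), source = "test", score = NA_real_,
    stringsAsFactors = FALSE
  )
}
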