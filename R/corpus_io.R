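# Document model and standoff I/O.
#
# A corpus is a data.frame with one row per block:
#   doc_id      document identifier (non-empty, unique per document)
#   block_index 0-based position of the block within its document
#   kind        one of "paragraph", "title", "table", "figure_caption"
#   text        the block text, preserved byte-for-byte from input
#
# Sentences, mentions and groundings are flat data.frames as well; all
# offsets are 0-based, half-open, in characters.

BLOCK_KINDS <- c("paragraph", "title", "table", "figure_caption")

#' Load documents into a corpus table
#'
#' Two input layouts are supported. `format = "plain"`: `path` is a text file
#' or a directory of `.txt` files; each file becomes one document whose
#' blank-line-separated chunks become paragraph blocks. `format = "blocks"`:
#' `path` is a line-delimited JSON file where each line carries
#' `doc_id`, `kind` and `text` for one block (block order within a document
#' follows file order).
#'
#' @param path file or directory to read.
#' @param format `"plain"` or `"blocks"`.
#' @return a corpus data.frame with columns `doc_id`, `block_index`, `kind`,
#'   `text`. Input text is preserved exactly inside each block.
#' @export
load_documents <- function(path, format = c("plain", "blocks")) {
  format <- match.arg(format)
  if (!file.exists(path)) input_error("cannot read corpus path: ", path)
  if (format == "plain") {
    files <- if (dir.exists(path)) {
      sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    } else {
      path
    }
    if (!length(files)) input_error("no .txt files under ", path)
    out <- lapply(files, function(f) {
      raw <- readChar(f, file.info(f)$size, useBytes = FALSE)
      raw <- gsub("\r\n", "\n", raw, fixed = TRUE)
      chunks <- strsplit(raw, "\n[[:space:]]*\n", perl = TRUE)[[1]]
      chunks <- chunks[nzchar(trimws(chunks))]
      chunks <- sub("^\n+", "", sub("\n+$", "", chunks))
      if (!length(chunks)) {
        validation_error("document with zero blocks rejected: ", f)
      }
      data.frame(
        doc_id = tools::file_path_sans_ext(basename(f)),
        block_index = seq_along(chunks) - 1L,
        kind = "paragraph", text = chunks, stringsAsFactors = FALSE
      )
    })
    corpus <- do.call(rbind, out)
  } else {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) validation_error("document with zero blocks rejected: ", path)
    recs <- lapply(lines, jsonlite::fromJSON)
    corpus <- data.frame(
      doc_id = vapply(recs, function(r) as.character(r$doc_id), ""),
      kind = vapply(recs, function(r) as.character(r$kind %||% "paragraph"), ""),
      text = vapply(recs, function(r) as.character(r$text), ""),
      stringsAsFactors = FALSE
    )
    corpus$block_index <- stats::ave(
      seq_len(nrow(corpus)), corpus$doc_id, FUN = seq_along
    ) - 1L
    corpus <- corpus[, c("doc_id", "block_index", "kind", "text")]
  }
  validate_corpus(corpus)
  corpus
}

#' Write a corpus in the line-delimited blocks format
#'
#' @param corpus corpus data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_documents <- function(corpus, path) {
  validate_corpus(corpus)
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    jsonlite::toJSON(list(
      doc_id = corpus$doc_id[i], kind = corpus$kind[i], text = corpus$text[i]
    ), auto_unbox = TRUE)
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @noRd
validate_corpus <- function(corpus) {
  req <- c("doc_id", "block_index", "kind", "text")
  miss <- setdiff(req, names(corpus))
  if (length(miss)) validation_error("corpus missing columns: ", paste(miss, collapse = ", "))
  if (!nrow(corpus)) validation_error("corpus has no blocks")
  if (any(!nzchar(corpus$doc_id))) validation_error("empty doc_id in corpus")
  if (any(!nzchar(corpus$text))) validation_error("empty block text in corpus")
  bad <- !corpus$kind %in% BLOCK_KINDS
  if (any(bad)) validation_error("unknown block kind: ", paste(unique(corpus$kind[bad]), collapse = ", "))
  ok <- tapply(corpus$block_index, corpus$doc_id, function(b) identical(sort(b), seq_along(b) - 1L))
  if (!all(unlist(ok))) validation_error("block_index must equal block position within each document")
  invisible(corpus)
}

#' Protected abbreviations for the sentence splitter
#'
#' Reads the abbreviation list shipped with the package (one entry per line,
#' `#` comments allowed). A sentence break candidate whose preceding text ends
#' with one of these strings is suppressed.
#'
#' @param path optional path to a custom list; defaults to the shipped file.
#' @return character vector of protected abbreviations.
#' @export
default_abbreviations <- function(path = NULL) {
  path <- path %||% system.file("extdata", "abbreviations.txt", package = "litmine")
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

# split one paragraph-like block; returns 0-based [start,end) sentence spans
split_block_prose <- function(text, abbreviations) {
  n <- nchar(text)
  if (!nzchar(trimws(text))) return(integer(0))
  # candidate breaks: terminator run followed by whitespace then uppercase/digit
  loc <- stringi::stri_locate_all_regex(text, "[.?!]+(?=[[:space:]]+[A-Z0-9])")[[1]]
  breaks <- integer(0)
  if (!all(is.na(loc[, 1]))) {
    for (k in seq_len(nrow(loc))) {
      endpos <- loc[k, 2] # 1-based position of last terminator char
      head_txt <- substr(text, 1L, endpos)
      protected <- FALSE
      for (ab in abbreviations) {
        if (endsWith(head_txt, ab)) {
          # require the abbreviation to start at a word boundary
          pre <- substr(head_txt, nchar(head_txt) - nchar(ab), nchar(head_txt) - nchar(ab))
          if (pre == "" || grepl("[^[:alnum:]]", pre)) { protected <- TRUE; break }
        }
      }
      if (!protected) {
        # single capital letter + period protection (species-style "E. coli")
        # only applies when the following word is lowercase, which the break
        # pattern already excludes; kept for custom terminator runs
        breaks <- c(breaks, endpos)
      }
    }
  }
  # build spans: sentence i runs from first non-space after previous break
  # through its break (inclusive); last sentence through trailing non-space
  starts <- integer(0); ends <- integer(0)
  cursor <- 1L
  bounds <- c(breaks, n)
  for (b in unique(bounds)) {
    seg <- substr(text, cursor, b)
    lead <- stringi::stri_locate_first_regex(seg, "[^[:space:]]")[1, 1]
    if (!is.na(lead)) {
      s <- cursor + lead - 1L
      seg2 <- substr(text, s, b)
      trail <- stringi::stri_locate_last_regex(seg2, "[^[:space:]]")[1, 1]
      e <- s + trail - 1L
      starts <- c(starts, s - 1L) # to 0-based
      ends <- c(ends, e)          # half-open end == 1-based inclusive pos
    }
    cursor <- b + 1L
  }
  cbind(start = starts, end = ends)
}

# table blocks: one sentence-unit per newline-delimited row
split_block_table <- function(text) {
  n <- nchar(text)
  nl <- c(stringi::stri_locate_all_fixed(text, "\n")[[1]][, 1])
  bounds <- c(if (!all(is.na(nl))) nl else integer(0), n + 1L)
  bounds <- bounds[!is.na(bounds)]
  starts <- integer(0); ends <- integer(0)
  cursor <- 1L
  for (b in bounds) {
    row_txt <- substr(text, cursor, b - 1L)
    lead <- stringi::stri_locate_first_regex(row_txt, "[^[:space:]]")[1, 1]
    if (!is.na(lead)) {
      s <- cursor + lead - 1L
      trail <- stringi::stri_locate_last_regex(substr(text, s, b - 1L), "[^[:space:]]")[1, 1]
      starts <- c(starts, s - 1L)
      ends <- c(ends, s + trail - 1L)
    }
    cursor <- b + 1L
  }
  cbind(start = starts, end = ends)
}

#' Split a corpus into sentences
#'
#' Rule-based splitting: a sentence ends at a `.?!` run followed by
#' whitespace and an uppercase letter or digit, unless the preceding text
#' ends with a protected abbreviation (see [default_abbreviations()]); the
#' next-character case requirement already protects species abbreviations
#' such as "E. coli". Table blocks are segmented one sentence-unit per
#' newline-delimited row; figure captions and titles are treated like
#' paragraphs. Whitespace-only blocks yield zero sentences.
#'
#' @param corpus corpus data.frame (see [load_documents()]).
#' @param abbreviations protected abbreviation list.
#' @return data.frame with columns `doc_id`, `block_index`, `sent_index`,
#'   `char_start`, `char_end` (0-based half-open into the block text), `text`.
#' @export
split_sentences <- function(corpus, abbreviations = default_abbreviations()) {
  validate_corpus(corpus)
  out <- vector("list", nrow(corpus))
  for (i in seq_len(nrow(corpus))) {
    txt <- corpus$text[i]
    spans <- if (corpus$kind[i] == "table") {
      split_block_table(txt)
    } else {
      split_block_prose(txt, abbreviations)
    }
    if (is.null(dim(spans)) || nrow(spans) == 0) next
    out[[i]] <- data.frame(
      doc_id = corpus$doc_id[i], block_index = corpus$block_index[i],
      sent_index = seq_len(nrow(spans)) - 1L,
      char_start = as.integer(spans[, "start"]),
      char_end = as.integer(spans[, "end"]),
      text = slice_chars(txt, spans[, "start"], spans[, "end"]),
      stringsAsFactors = FALSE
    )
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) {
    return(data.frame(doc_id = character(), block_index = integer(),
                      sent_index = integer(), char_start = integer(),
                      char_end = integer(), text = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Read gold-standard mention spans (standoff TSV)
#'
#' Expects tab-separated columns `doc_id`, `block_index`, `char_start`,
#' `char_end`, `entity_type`, `surface`, with offsets 0-based half-open into
#' the block text. Every row is validated against the paired corpus: the
#' offsets must lie inside the block and `surface` must equal the corpus
#' slice. When `sentences` are supplied, each mention is located inside its
#' containing sentence (sentence-relative offsets); mentions crossing
#' sentence boundaries keep `NA` sentence locators.
#'
#' @param path gold TSV path.
#' @param corpus the corpus the spans refer to.
#' @param sentences optional output of [split_sentences()] for locating
#'   mentions within sentences.
#' @return a mention data.frame (see package docs for columns). Empty file
#'   yields an empty mention table.
#' @export
read_gold <- function(path, corpus, sentences = NULL) {
  if (!file.exists(path)) input_error("cannot read gold file: ", path)
  validate_corpus(corpus)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character", stringsAsFactors = FALSE)
  if (!nrow(tab)) return(empty_mentions())
  req <- c("doc_id", "block_index", "char_start", "char_end", "entity_type", "surface")
  miss <- setdiff(req, names(tab))
  if (length(miss)) validation_error("gold file missing columns: ", paste(miss, collapse = ", "))
  key <- paste(corpus$doc_id, corpus$block_index)
  block_of <- match(paste(tab$doc_id, tab$block_index), key)
  starts <- suppressWarnings(as.integer(tab$char_start))
  ends <- suppressWarnings(as.integer(tab$char_end))
  for (i in seq_len(nrow(tab))) {
    row_lbl <- paste0("gold row ", i)
    if (is.na(block_of[i])) {
      validation_error(row_lbl, ": unknown document/block ",
                       tab$doc_id[i], "/", tab$block_index[i])
    }
    if (!tab$entity_type[i] %in% ENTITY_TYPES) {
      validation_error(row_lbl, ": unknown entity type '", tab$entity_type[i], "'")
    }
    blk <- corpus$text[block_of[i]]
    if (is.na(starts[i]) || is.na(ends[i]) || starts[i] < 0 ||
        ends[i] <= starts[i] || ends[i] > nchar(blk)) {
      validation_error(row_lbl, ": offsets [", tab$char_start[i], ",",
                       tab$char_end[i], ") outside block of length ", nchar(blk))
    }
    sl <- slice_chars(blk, starts[i], ends[i])
    if (!identical(sl, tab$surface[i])) {
      validation_error(row_lbl, ": surface '", tab$surface[i],
                       "' does not equal corpus slice '", sl, "'")
    }
  }
  m <- data.frame(
    doc_id = tab$doc_id, block_index = as.integer(tab$block_index),
    sent_index = NA_integer_, entity_type = tab$entity_type,
    char_start = NA_integer_, char_end = NA_integer_,
    block_start = starts, block_end = ends, surface = tab$surface,
    source = "gold", score = NA_real_, stringsAsFactors = FALSE
  )
  if (!is.null(sentences)) m <- locate_in_sentences(m, sentences)
  m
}

#' Write gold-standard mention spans (standoff TSV)
#'
#' @param mentions mention data.frame with block-relative offsets.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_gold <- function(mentions, path) {
  check_mentions(mentions, "gold mentions")
  out <- data.frame(
    doc_id = mentions$doc_id, block_index = mentions$block_index,
    char_start = mentions$block_start, char_end = mentions$block_end,
    entity_type = mentions$entity_type, surface = mentions$surface,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# fill sent_index + sentence-relative offsets for mentions contained in a
# single sentence; others keep NA
locate_in_sentences <- function(mentions, sentences) {
  if (!nrow(mentions)) return(mentions)
  skey <- paste(sentences$doc_id, sentences$block_index)
  for (i in seq_len(nrow(mentions))) {
    cand <- which(skey == paste(mentions$doc_id[i], mentions$block_index[i]) &
                    sentences$char_start <= mentions$block_start[i] &
                    sentences$char_end >= mentions$block_end[i])
    if (length(cand) == 1L) {
      mentions$sent_index[i] <- sentences$sent_index[cand]
      mentions$char_start[i] <- mentions$block_start[i] - sentences$char_start[cand]
      mentions$char_end[i] <- mentions$block_end[i] - sentences$char_start[cand]
    }
  }
  mentions
}

ANNOTATION_FIELDS <- c("doc_id", "block_index", "sent_index", "char_start",
                       "char_end", "type", "exact", "prefix", "postfix",
                       "id", "method", "confidence")

#' Write annotations as line-delimited JSON
#'
#' One record per mention with the fields `doc_id`, `block_index`,
#' `sent_index`, `char_start`, `char_end` (sentence-relative, 0-based
#' half-open), `type`, `exact` (the surface string), `prefix`/`postfix`
#' (up to 20 characters of context on each side, clipped at the sentence
#' boundaries), `id` (grounded identifier or `"UNMAPPED"`), `method` and
#' `confidence`. Records round-trip through [read_annotations()].
#'
#' @param groundings grounding (or plain mention) data.frame; mentions
#'   without grounding columns are written with `id = "UNMAPPED"`.
#' @param sentences sentence table covering every mention, used for context.
#' @param path output file.
#' @param context_chars context width on each side (default 20).
#' @return `path`, invisibly.
#' @export
write_annotations <- function(groundings, sentences, path, context_chars = 20L) {
  con <- tryCatch(file(path, open = "wb"), error = function(e)
    lm_stop("cannot open annotation sink: ", path, class = "litmine_io_error"))
  on.exit(close(con))
  if (!nrow(groundings)) {
    return(invisible(path))
  }
  check_mentions(groundings, "groundings")
  skey <- paste(sentences$doc_id, sentences$block_index, sentences$sent_index)
  gkey <- paste(groundings$doc_id, groundings$block_index, groundings$sent_index)
  sid <- match(gkey, skey)
  if (anyNA(sid)) validation_error("grounding references a sentence not present in `sentences`")
  lines <- character(nrow(groundings))
  for (i in seq_len(nrow(groundings))) {
    stext <- sentences$text[sid[i]]
    s <- groundings$char_start[i]; e <- groundings$char_end[i]
    rec <- list(
      doc_id = groundings$doc_id[i],
      block_index = groundings$block_index[i],
      sent_index = groundings$sent_index[i],
      char_start = s, char_end = e,
      type = groundings$entity_type[i],
      exact = groundings$surface[i],
      prefix = slice_chars(stext, max(0L, s - context_chars), s),
      postfix = slice_chars(stext, e, min(nchar(stext), e + context_chars)),
      id = if (!is.null(groundings$entry_id)) groundings$entry_id[i] else "UNMAPPED",
      method = if (!is.null(groundings$method)) groundings$method[i] else "unmapped",
      confidence = if (!is.null(groundings$confidence)) groundings$confidence[i] else 0
    )
    lines[i] <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  }
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Read annotations written by [write_annotations()]
#'
#' @param path line-delimited JSON annotation file.
#' @param sentences optional sentence table; when given, block-relative
#'   offsets are reconstructed so the result round-trips to the original
#'   mention set.
#' @return grounding data.frame.
#' @export
read_annotations <- function(path, sentences = NULL) {
  if (!file.exists(path)) input_error("cannot read annotations: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    g <- empty_mentions()
    g$entry_id <- character(); g$method <- character(); g$confidence <- numeric()
    return(g)
  }
  recs <- lapply(lines, jsonlite::fromJSON)
  g <- data.frame(
    doc_id = vapply(recs, function(r) as.character(r$doc_id), ""),
    block_index = vapply(recs, function(r) as.integer(r$block_index), 0L),
    sent_index = vapply(recs, function(r) as.integer(r$sent_index), 0L),
    entity_type = vapply(recs, function(r) as.character(r$type), ""),
    char_start = vapply(recs, function(r) as.integer(r$char_start), 0L),
    char_end = vapply(recs, function(r) as.integer(r$char_end), 0L),
    block_start = NA_integer_, block_end = NA_integer_,
    surface = vapply(recs, function(r) as.character(r$exact), ""),
    source = "annotation", score = NA_real_,
    entry_id = vapply(recs, function(r) as.character(r$id), ""),
    method = vapply(recs, function(r) as.character(r$method), ""),
    confidence = vapply(recs, function(r) as.numeric(r$confidence), 0),
    stringsAsFactors = FALSE
  )
  if (!is.null(sentences)) {
    skey <- paste(sentences$doc_id, sentences$block_index, sentences$sent_index)
    sid <- match(paste(g$doc_id, g$block_index, g$sent_index), skey)
    ok <- !is.na(sid)
    g$block_start[ok] <- sentences$char_start[sid[ok]] + g$char_start[ok]
    g$block_end[ok] <- sentences$char_start[sid[ok]] + g$char_end[ok]
  }
  g
}
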