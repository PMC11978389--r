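# Tokenization and skip-gram word embeddings over the working corpus.

#' Tokenize text
#'
#' Lowercases and extracts maximal runs of alphanumeric characters, keeping
#' internal hyphens ("non-small" stays one token). Order is preserved.
#'
#' @param text character vector.
#' @return for a single string, a character vector of tokens; for longer
#'   input, a list of token vectors.
#' @export
tokenize <- function(text) {
  toks <- stringi::stri_extract_all_regex(
    stringi::stri_trans_tolower(text),
    "[[:alnum:]]+(?:-[[:alnum:]]+)*"
  )
  toks <- lapply(toks, function(t) if (length(t) == 1 && is.na(t)) character(0) else t)
  if (length(text) == 1L) toks[[1]] else toks
}

#' Skip-gram training parameters
#'
#' @param dim embedding dimension (default 100).
#' @param window symmetric context window size (default 5).
#' @param negative_samples negative samples per positive pair (default 5).
#' @param epochs passes over the corpus (default 5).
#' @param min_count minimum token frequency to enter the vocabulary
#'   (default 2).
#' @param seed RNG seed for initialization, window reduction, subsampling
#'   and negative sampling; identical corpus + params + seed give
#'   bitwise-identical vectors (training is single-threaded).
#' @param learning_rate initial SGD learning rate, decayed linearly
#'   (default 0.025).
#' @param subsample frequent-word subsampling threshold (word2vec `sample`;
#'   default 1e-3, 0 disables). Tokens with relative frequency `f` are kept
#'   with probability `(sqrt(f/t) + 1) * t/f`, which stops very frequent
#'   function words from dominating the training pairs.
#' @return object of class `litmine_embedding_params`.
#' @export
embedding_params <- function(dim = 100L, window = 5L, negative_samples = 5L,
                             epochs = 5L, min_count = 2L, seed = 1L,
                             learning_rate = 0.025, subsample = 1e-3) {
  p <- list(dim = as.integer(dim), window = as.integer(window),
            negative_samples = as.integer(negative_samples),
            epochs = as.integer(epochs), min_count = as.integer(min_count),
            seed = as.integer(seed), learning_rate = as.numeric(learning_rate),
            subsample = as.numeric(subsample))
  if (p$dim < 1 || p$window < 1 || p$epochs < 1 || p$min_count < 1 ||
      p$negative_samples < 0 || p$learning_rate <= 0 || p$subsample < 0) {
    validation_error("invalid embedding parameters")
  }
  structure(p, class = "litmine_embedding_params")
}

#' Train skip-gram embeddings
#'
#' Skip-gram with negative sampling over a symmetric context window,
#' single-threaded, so identical corpus, parameters and seed yield
#' bitwise-identical vectors. Tokens below `min_count` are excluded from the
#' vocabulary and skipped during training.
#'
#' @param sentences a list of character token vectors, or a character vector
#'   of raw sentence texts (then run through [tokenize()]).
#' @param params an [embedding_params()] object.
#' @return object of class `litmine_embeddings`: list with `vectors`
#'   (matrix, one named row per vocabulary token), `params`, `counts`.
#' @export
train_embeddings <- function(sentences, params = embedding_params()) {
  if (is.character(sentences)) {
    sentences <- tokenize(sentences)
    if (!is.list(sentences)) sentences <- list(sentences)
  }
  sentences <- lapply(sentences, as.character)
  sentences <- sentences[vapply(sentences, length, 0L) > 0]
  if (!length(sentences)) validation_error("cannot train embeddings on an empty corpus")
  counts <- table(unlist(sentences, use.names = FALSE))
  counts <- counts[counts >= params$min_count]
  if (!length(counts)) {
    validation_error("no token reaches min_count = ", params$min_count)
  }
  # frequency-descending, then lexicographic: a deterministic vocabulary order
  vocab <- names(counts)[order(-as.integer(counts), names(counts))]
  counts <- as.numeric(counts[vocab])
  ids <- seq_along(vocab) - 1L
  names(ids) <- vocab
  sent_ids <- lapply(sentences, function(s) {
    v <- ids[s]
    as.integer(v[!is.na(v)])
  })
  sent_ids <- sent_ids[vapply(sent_ids, length, 0L) > 0]
  mats <- if (length(sent_ids)) {
    .sgns_train_cpp(sent_ids, length(vocab), counts, params$dim, params$window,
                    params$negative_samples, params$epochs,
                    params$learning_rate, params$subsample, params$seed)
  } else {
    list(input = matrix(0, nrow = length(vocab), ncol = params$dim),
         output = matrix(0, nrow = length(vocab), ncol = params$dim))
  }
  rownames(mats$input) <- vocab
  rownames(mats$output) <- vocab
  structure(list(vectors = mats$input, output_vectors = mats$output,
                 params = params, counts = stats::setNames(counts, vocab)),
            class = "litmine_embeddings")
}

#' @export
print.litmine_embeddings <- function(x, ...) {
  cat(sprintf("<litmine_embeddings vocab=%d dim=%d>\n",
              nrow(x$vectors), ncol(x$vectors)))
  invisible(x)
}

#' Phrase vector: mean of in-vocabulary token vectors
#'
#' @param model a `litmine_embeddings`.
#' @param text phrase string (tokenized internally) or a character vector of
#'   tokens.
#' @param space `"input"` (default) for the word vectors proper, suited to
#'   interchangeability-style similarity; `"output"` for the context matrix,
#'   whose dot products with input vectors score first-order co-occurrence
#'   (used by the grounding context-disambiguation tier).
#' @return numeric vector of length `dim`, or `NULL` when no token of the
#'   phrase is in the vocabulary.
#' @export
phrase_vector <- function(model, text, space = c("input", "output")) {
  space <- match.arg(space)
  mat <- if (space == "output" && !is.null(model$output_vectors)) {
    model$output_vectors
  } else {
    model$vectors
  }
  toks <- if (length(text) > 1L) stringi::stri_trans_tolower(text) else tokenize(text)
  toks <- toks[toks %in% rownames(mat)]
  if (!length(toks)) return(NULL)
  colMeans(mat[toks, , drop = FALSE])
}

# training keep-probability of each token under the model's subsampling
# threshold: min(1, (sqrt(f/t)+1) * t/f). Frequent function words get small
# weights, informative rare tokens weight 1. Falls back to uniform weights
# when counts or a positive threshold are unavailable.
subsample_weights <- function(model, tokens) {
  thr <- model$params$subsample %||% 0
  if (is.null(model$counts) || thr <= 0) {
    return(stats::setNames(rep(1, length(tokens)), tokens))
  }
  f <- model$counts[tokens] / sum(model$counts)
  w <- pmin((sqrt(f / thr) + 1) * thr / f, 1)
  w[is.na(w)] <- 1
  stats::setNames(as.numeric(w), tokens)
}

# subsample-weighted mean vector over in-vocabulary tokens; the grounding
# context-disambiguation tier uses this with space = "output" on labels
weighted_phrase_vector <- function(model, tokens, space = "input") {
  mat <- if (space == "output" && !is.null(model$output_vectors)) {
    model$output_vectors
  } else {
    model$vectors
  }
  tokens <- tokens[tokens %in% rownames(mat)]
  if (!length(tokens)) return(NULL)
  w <- subsample_weights(model, tokens)
  if (sum(w) <= 0) return(NULL)
  colSums(mat[tokens, , drop = FALSE] * as.numeric(w)) / sum(w)
}

#' Persist an embedding model as text
#'
#' Line 1 is a JSON header with the training parameters; then one
#' `token<TAB>v1 v2 ...` line per vocabulary token (input vectors), a
#' `#output` separator, and the output-matrix rows in the same format. All
#' values are written at full precision, so write/read round-trips exactly.
#'
#' @param model a `litmine_embeddings`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(model, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(as.character(jsonlite::toJSON(unclass(model$params), auto_unbox = TRUE, digits = NA)), con)
  fmt_rows <- function(mat) {
    vapply(seq_len(nrow(mat)), function(i) {
      paste0(rownames(mat)[i], "\t",
             paste(format(mat[i, ], digits = 17, trim = TRUE,
                          scientific = TRUE), collapse = " "))
    }, "")
  }
  if (!is.null(model$counts)) {
    writeLines("#counts", con)
    writeLines(paste0(names(model$counts), "\t",
                      format(model$counts, digits = 17, trim = TRUE)), con,
               useBytes = TRUE)
  }
  writeLines("#input", con)
  writeLines(fmt_rows(model$vectors), con, useBytes = TRUE)
  if (!is.null(model$output_vectors)) {
    writeLines("#output", con)
    writeLines(fmt_rows(model$output_vectors), con, useBytes = TRUE)
  }
  invisible(path)
}

#' Read an embedding model written by [write_embeddings()]
#' @param path model file.
#' @return a `litmine_embeddings` (token counts are not persisted).
#' @export
read_embeddings <- function(path) {
  if (!file.exists(path)) input_error("cannot read embeddings: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  params <- do.call(embedding_params, jsonlite::fromJSON(lines[1]))
  body <- lines[-1]
  body <- body[nzchar(body)]
  marks <- which(startsWith(body, "#"))
  sections <- list()
  for (k in seq_along(marks)) {
    from <- marks[k] + 1L
    to <- if (k < length(marks)) marks[k + 1L] - 1L else length(body)
    if (from <= to) sections[[sub("^#", "", body[marks[k]])]] <- body[from:to]
  }
  parse_rows <- function(rows) {
    parts <- strsplit(rows, "\t", fixed = TRUE)
    vecs <- t(vapply(parts, function(p) as.numeric(strsplit(p[[2]], " ", fixed = TRUE)[[1]]),
                     numeric(params$dim)))
    rownames(vecs) <- vapply(parts, `[[`, "", 1L)
    vecs
  }
  counts <- NULL
  if (!is.null(sections$counts)) {
    parts <- strsplit(sections$counts, "\t", fixed = TRUE)
    counts <- stats::setNames(vapply(parts, function(p) as.numeric(p[[2]]), 0),
                              vapply(parts, `[[`, "", 1L))
  }
  input <- parse_rows(sections$input %||% body[!startsWith(body, "#")])
  output <- if (!is.null(sections$output)) parse_rows(sections$output) else NULL
  structure(list(vectors = input, output_vectors = output, params = params,
                 counts = counts),
            class = "litmine_embeddings")
}
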