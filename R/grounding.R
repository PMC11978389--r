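# Grounding (normalization): map tagged mentions to lexicon identifiers
# through an ordered lexical cascade, with skip-gram embeddings used for
# ambiguity resolution and as a semantic fallback tier.
#
# Cascade tiers (each independently switchable):
#   exact     normalized surface equals a preferred label -> confidence 1.0
#   synonym   normalized surface is an indexed term; unambiguous -> 0.9;
#             ambiguous -> candidate whose preferred-label vector (weighted
#             mean in the skip-gram output space) is most similar to the
#             mention's sentence-context vector (weighted mean input
#             vectors, mention tokens excluded); confidence = that
#             similarity, clamped to [0, 1]
#   fuzzy     unique index term within edit distance <= fuzzy_max_distance,
#             with a single candidate id -> 0.7
#   embedding nearest lexicon entry by cosine between the surface phrase
#             vector and preferred-label phrase vectors, accepted iff the
#             similarity reaches tau (confidence = similarity)
# Anything else is UNMAPPED. The exact constants are package conventions
# chosen so that confidence is monotone in tier reliability.

#' Grounding policy
#'
#' @param tau acceptance threshold for the embedding tier, in \[0, 1\]
#'   (default 0.5). Raising `tau` never increases the mapped count.
#' @param cascade ordered subset of
#'   `c("exact", "synonym", "fuzzy", "embedding")`; tiers fire in this order.
#' @param fuzzy_max_distance maximum Levenshtein distance for the fuzzy tier
#'   (default 1).
#' @return object of class `litmine_grounding_policy`.
#' @export
grounding_policy <- function(tau = 0.5,
                             cascade = c("exact", "synonym", "fuzzy", "embedding"),
                             fuzzy_max_distance = 1L) {
  cascade <- match.arg(cascade, several.ok = TRUE)
  if (!length(cascade)) validation_error("cascade must name at least one tier")
  if (tau < 0 || tau > 1) validation_error("tau must lie in [0, 1]")
  structure(list(tau = tau, cascade = cascade,
                 fuzzy_max_distance = as.integer(fuzzy_max_distance)),
            class = "litmine_grounding_policy")
}

# preferred-label phrase vectors for a lexicon, as a matrix (may contain NA
# rows for labels fully out of vocabulary). `space = "output"` with
# `weighted = TRUE` gives the subsample-weighted context-matrix vectors used
# by the disambiguation tier: their similarity against input-space context
# vectors scores co-occurrence affinity rather than interchangeability.
label_vectors <- function(lexicon, model, space = "input", weighted = FALSE) {
  if (is.null(model)) return(NULL)
  labs <- lexicon$entries$preferred_label
  out <- matrix(NA_real_, nrow = length(labs), ncol = ncol(model$vectors),
                dimnames = list(lexicon$entries$entry_id, NULL))
  for (i in seq_along(labs)) {
    v <- if (weighted) {
      weighted_phrase_vector(model, tokenize(labs[i]), space = space)
    } else {
      phrase_vector(model, labs[i], space = space)
    }
    if (!is.null(v)) out[i, ] <- v
  }
  out
}

# pick among candidate ids by cosine(label vector, context vector);
# deterministic fallback: lexicographically smallest id, confidence 0.5
disambiguate <- function(ids, context_vec, labvecs) {
  ids <- sort(ids)
  if (is.null(labvecs) || is.null(context_vec)) {
    return(list(id = ids[1L], confidence = 0.5))
  }
  sims <- vapply(ids, function(id) {
    v <- labvecs[id, ]
    if (anyNA(v)) return(NA_real_)
    cosine_similarity(v, context_vec)
  }, 0)
  if (all(is.na(sims))) return(list(id = ids[1L], confidence = 0.5))
  best <- which(sims == max(sims, na.rm = TRUE))[1L]
  list(id = ids[best], confidence = max(0, min(1, sims[best])))
}

#' Ground a single mention
#'
#' Runs the cascade of `policy` against `lexicon` (whose entity type must
#' equal the mention's). The sentence text, when available, supplies the
#' context vector used to resolve ambiguous terms: the mean embedding of the
#' sentence tokens excluding the mention's own tokens.
#'
#' @param mention one-row mention data.frame (needs `surface` and
#'   `entity_type`).
#' @param lexicon `litmine_lexicon` of the same entity type.
#' @param model optional `litmine_embeddings`.
#' @param policy a [grounding_policy()].
#' @param sentence_text optional sentence string containing the mention.
#' @return list with `entry_id` (or `"UNMAPPED"`), `method`, `confidence`.
#' @export
ground_mention <- function(mention, lexicon, model = NULL,
                           policy = grounding_policy(), sentence_text = NULL) {
  surface <- mention$surface
  if (!identical(mention$entity_type, lexicon$entity_type)) {
    validation_error("mention type ", mention$entity_type,
                     " does not match lexicon type ", lexicon$entity_type)
  }
  ground_surface(surface, lexicon, model, policy,
                 context_vec = context_vector(model, sentence_text, surface),
                 labvecs = label_vectors(lexicon, model),
                 labvecs_out = label_vectors(lexicon, model, space = "output",
                                             weighted = TRUE))
}

# context vector of a mention: subsample-weighted mean of the input vectors
# of the sentence tokens, excluding the mention's own tokens. The weighting
# reuses the trainer's keep probabilities, so frequent function words
# contribute little and co-mentioned entities dominate.
context_vector <- function(model, sentence_text, surface) {
  if (is.null(model) || is.null(sentence_text)) return(NULL)
  stoks <- tokenize(sentence_text)
  mtoks <- tokenize(surface)
  for (t in mtoks) {
    hit <- match(t, stoks)
    if (!is.na(hit)) stoks <- stoks[-hit]
  }
  if (!length(stoks)) return(NULL)
  weighted_phrase_vector(model, stoks)
}

# cascade core over a bare surface string; `labvecs` (input space) feeds the
# embedding fallback tier, `labvecs_out` (output space) the context
# disambiguation of ambiguous terms
ground_surface <- function(surface, lexicon, model, policy, context_vec,
                           labvecs, labvecs_out = labvecs) {
  norm <- normalize_term(surface)
  pref_norm <- normalize_term(lexicon$entries$preferred_label)
  for (tier in policy$cascade) {
    if (tier == "exact") {
      hit <- lexicon$entries$entry_id[pref_norm == norm]
      if (length(hit) == 1L) {
        return(list(entry_id = hit, method = "exact", confidence = 1.0))
      }
      if (length(hit) > 1L) {
        d <- disambiguate(hit, context_vec, labvecs_out)
        return(list(entry_id = d$id, method = "exact", confidence = 1.0))
      }
    } else if (tier == "synonym") {
      ids <- lexicon_lookup(lexicon, surface)
      if (length(ids) == 1L) {
        return(list(entry_id = ids, method = "synonym", confidence = 0.9))
      }
      if (length(ids) > 1L) {
        d <- disambiguate(ids, context_vec, labvecs_out)
        return(list(entry_id = d$id, method = "synonym", confidence = d$confidence))
      }
    } else if (tier == "fuzzy") {
      terms <- lexicon_terms(lexicon)
      dist <- utils::adist(norm, terms)[1, ]
      close <- terms[dist > 0 & dist <= policy$fuzzy_max_distance]
      if (length(close) == 1L) {
        ids <- lexicon$term_index[[close]]
        if (length(ids) == 1L) {
          return(list(entry_id = ids, method = "fuzzy", confidence = 0.7))
        }
      }
    } else if (tier == "embedding") {
      if (is.null(model) || is.null(labvecs)) next
      sv <- phrase_vector(model, surface)
      if (is.null(sv)) next
      sims <- vapply(seq_len(nrow(labvecs)), function(i) {
        v <- labvecs[i, ]
        if (anyNA(v)) return(NA_real_)
        cosine_similarity(v, sv)
      }, 0)
      if (all(is.na(sims))) next
      best <- which(sims == max(sims, na.rm = TRUE))[1L]
      if (!is.na(sims[best]) && sims[best] >= policy$tau) {
        return(list(entry_id = rownames(labvecs)[best], method = "embedding",
                    confidence = max(0, min(1, sims[best]))))
      }
    }
  }
  list(entry_id = "UNMAPPED", method = "unmapped", confidence = 0)
}

#' Ground every groundable mention of a corpus
#'
#' Mentions of type GP, DS and CD are grounded against the lexicon of their
#' type; organism (OG) mentions pass through untouched (they are not part of
#' the grounded output). Every groundable mention lands exactly once in
#' either the mapped groundings or the failed list.
#'
#' @param mentions mention data.frame (e.g. from [tag_corpus()]).
#' @param lexicons named list of lexicons keyed by entity type
#'   (`GP`, `DS`, `CD`), or an unnamed list (keyed by each lexicon's type).
#' @param model optional `litmine_embeddings` for disambiguation/fallback.
#' @param policy a [grounding_policy()].
#' @param sentences optional sentence table supplying context text.
#' @return list with `groundings` (mentions + `entry_id`, `method`,
#'   `confidence`; includes UNMAPPED rows) and `failed` (the UNMAPPED subset
#'   with a `sentence_text` column, mirroring a failed-co-occurrences export).
#' @export
ground_corpus <- function(mentions, lexicons, model = NULL,
                          policy = grounding_policy(), sentences = NULL) {
  if (inherits(lexicons, "litmine_lexicon")) lexicons <- list(lexicons)
  if (is.null(names(lexicons)) || any(!nzchar(names(lexicons)))) {
    names(lexicons) <- vapply(lexicons, function(l) l$entity_type, "")
  }
  g <- mentions[mentions$entity_type %in% GROUNDABLE_TYPES, , drop = FALSE]
  missing_types <- setdiff(unique(g$entity_type), names(lexicons))
  if (length(missing_types)) {
    validation_error("no lexicon supplied for groundable type(s): ",
                     paste(missing_types, collapse = ", "))
  }
  g$entry_id <- "UNMAPPED"; g$method <- "unmapped"; g$confidence <- 0
  stext <- rep(NA_character_, nrow(g))
  if (!is.null(sentences) && nrow(g)) {
    skey <- paste(sentences$doc_id, sentences$block_index, sentences$sent_index)
    sid <- match(paste(g$doc_id, g$block_index, g$sent_index), skey)
    stext[!is.na(sid)] <- sentences$text[sid[!is.na(sid)]]
  }
  labcache <- lapply(lexicons, label_vectors, model = model)
  labcache_out <- lapply(lexicons, label_vectors, model = model,
                         space = "output", weighted = TRUE)
  # memoize context-free groundings per (type, surface)
  memo <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(g))) {
    tt <- g$entity_type[i]
    lex <- lexicons[[tt]]
    ids_here <- lexicon_lookup(lex, g$surface[i])
    needs_context <- length(ids_here) > 1L
    key <- paste0(tt, "\r", g$surface[i])
    res <- NULL
    if (!needs_context) res <- memo[[key]]
    if (is.null(res)) {
      ctx <- if (needs_context) context_vector(model, stext[i], g$surface[i]) else NULL
      res <- ground_surface(g$surface[i], lex, model, policy,
                            context_vec = ctx, labvecs = labcache[[tt]],
                            labvecs_out = labcache_out[[tt]])
      if (!needs_context) memo[[key]] <- res
    }
    g$entry_id[i] <- res$entry_id
    g$method[i] <- res$method
    g$confidence[i] <- res$confidence
  }
  failed <- g[g$entry_id == "UNMAPPED", , drop = FALSE]
  failed$sentence_text <- stext[g$entry_id == "UNMAPPED"]
  list(groundings = g, failed = failed)
}

#' Write the failed (unmapped) mention export
#'
#' Line-delimited JSON records: the mention locator, surface, type and its
#' sentence text — the mentions that could not be normalized but remain
#' available for further study.
#'
#' @param failed `failed` element of [ground_corpus()] output.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_failed <- function(failed, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(failed)) {
    lines <- vapply(seq_len(nrow(failed)), function(i) {
      jsonlite::toJSON(list(
        doc_id = failed$doc_id[i], block_index = failed$block_index[i],
        sent_index = failed$sent_index[i], type = failed$entity_type[i],
        exact = failed$surface[i],
        sentence_text = if (is.na(failed$sentence_text[i])) NULL else failed$sentence_text[i]
      ), auto_unbox = TRUE, null = "null")
    }, "")
    writeLines(lines, con, useBytes = TRUE)
  }
  invisible(path)
}
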