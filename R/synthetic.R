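# Synthetic corpus generator: template-built abstracts with planted lexicon
# mentions at exact character offsets, plus the ground truth (gold spans
# with identifiers, true association set, per-sentence pair counts). Every
# stage of the pipeline is testable against this truth without downloads.
#
# Text is template-based, not language-model prose: span-exact offsets and
# a known truth are the whole point. Documents carry a "topic" (one GP, one
# DS, one CD entry reused across the document's sentences) so that skip-gram
# embeddings see consistent co-occurrence structure, which is what the
# context-disambiguation tier of the grounding cascade relies on.

# fixed filler vocabulary used by templates and unfilled slots; the lexicon
# generator never emits any of these strings as a term
TEMPLATE_WORDS <- c(
  "is", "associated", "with", "in", "patients", "treated", "expression",
  "was", "elevated", "treatment", "reduced", "progression", "inhibits",
  "activity", "studies", "linked", "to", "of", "measured", "the", "cohort",
  "followed", "for", "two", "years", "candidate", "marker", "studied",
  "condition", "assigned", "compound", "model", "organism", "a",
  "significant", "effect", "observed", "samples", "analysis", "revealed",
  "levels", "increased", "after", "therapy", "clinical", "trial", "data"
)

#' Generator configuration
#'
#' Defaults describe the reference study conditions used throughout the test
#' suite: 200 template-built documents of 5 sentences, four 50-entry
#' lexicons, slots filled at rate 0.9, no shared-synonym ambiguity and no
#' distractor noise, and an expected 1.5 mapped pairs per sentence.
#'
#' @param seed integer seed; the whole generation is deterministic under it.
#' @param n_documents,sentences_per_doc corpus shape.
#' @param lexicon_sizes named integer vector with entries `GP`, `DS`, `CD`,
#'   `OG`.
#' @param planting_rate probability that an entity slot in a template is
#'   filled with a lexicon term (otherwise a generic filler phrase).
#' @param ambiguity_rate probability that a generated entry's short synonym
#'   is shared with another entry of the same type (ambiguous term).
#' @param noise_rate probability that a sentence gains a spurious
#'   parenthetical lexicon mention that is *not* recorded in the gold truth
#'   (models dictionary-tagger false positives).
#' @param association_density expected number of mapped GP/DS/CD pairs per
#'   sentence, in \[0, 3\].
#' @return object of class `litmine_generator_config`.
#' @export
generator_config <- function(seed = 42L, n_documents = 200L,
                             sentences_per_doc = 5L,
                             lexicon_sizes = c(GP = 50L, DS = 50L, CD = 50L, OG = 50L),
                             planting_rate = 0.9, ambiguity_rate = 0,
                             noise_rate = 0, association_density = 1.5) {
  cfg <- list(seed = as.integer(seed), n_documents = as.integer(n_documents),
              sentences_per_doc = as.integer(sentences_per_doc),
              lexicon_sizes = lexicon_sizes,
              planting_rate = planting_rate, ambiguity_rate = ambiguity_rate,
              noise_rate = noise_rate, association_density = association_density)
  probs <- c(planting_rate, ambiguity_rate, noise_rate)
  if (any(probs < 0 | probs > 1)) validation_error("rates must lie in [0, 1]")
  if (association_density < 0 || association_density > 3) {
    validation_error("association_density must lie in [0, 3]")
  }
  if (cfg$n_documents < 1 || cfg$sentences_per_doc < 1) {
    validation_error("corpus shape must be positive")
  }
  if (!all(c("GP", "DS", "CD", "OG") %in% names(lexicon_sizes)) ||
      any(lexicon_sizes < 1)) {
    validation_error("lexicon_sizes needs positive GP, DS, CD, OG entries")
  }
  structure(cfg, class = "litmine_generator_config")
}

# pool of pronounceable unique nonsense words, disjoint from TEMPLATE_WORDS
make_word_pool <- function(n) {
  consonants <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s",
                  "t", "v", "z", "br", "dr", "gl", "kr", "pl", "tr")
  vowels <- c("a", "e", "i", "o", "u", "ae", "ia", "or")
  pool <- character(0)
  while (length(pool) < n) {
    k <- sample(2:3, 1)
    w <- paste0(vapply(seq_len(k), function(i) {
      paste0(sample(consonants, 1), sample(vowels, 1))
    }, ""), collapse = "")
    if (nchar(w) >= 4 && !(w %in% pool) && !(w %in% TEMPLATE_WORDS)) {
      pool <- c(pool, w)
    }
  }
  pool
}

# unique short all-caps codes, e.g. "QTR4"
make_code_pool <- function(n) {
  pool <- character(0)
  while (length(pool) < n) {
    code <- paste0(paste(sample(LETTERS, 3, replace = TRUE), collapse = ""),
                   sample(0:9, 1))
    if (!(code %in% pool)) pool <- c(pool, code)
  }
  pool
}

#' Generate synthetic lexicons
#'
#' Deterministic under `config$seed`. Labels include multi-word forms and
#' short all-uppercase synonyms; at `ambiguity_rate`, an entry's short
#' synonym is shared with an earlier entry of the same type, so the term
#' index maps it to two identifiers.
#'
#' @param config a [generator_config()].
#' @return named list of `litmine_lexicon` objects (`GP`, `DS`, `CD`, `OG`).
#' @export
generate_lexicons <- function(config) {
  with_seed(config$seed, {
    sizes <- config$lexicon_sizes
    total_words <- sum(sizes) * 3L + 40L
    words <- make_word_pool(total_words)
    codes <- make_code_pool(sum(sizes) * 2L)
    wi <- 0L; ci <- 0L
    take_word <- function() { wi <<- wi + 1L; words[wi] }
    take_code <- function() { ci <<- ci + 1L; codes[ci] }
    cap <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))

    build <- function(type, n, make_entry) {
      ids <- sprintf("SYN%s:%04d", type, seq_len(n))
      available_codes <- character(0) # codes owned by exactly one entry so far
      rows <- vector("list", n)
      for (i in seq_len(n)) {
        e <- make_entry(i)
        syn <- e$synonyms
        # shared-synonym ambiguity: adopt an earlier entry's code, and retire
        # it from the pool so every ambiguous term stays exactly two-way
        if (i > 1 && length(available_codes) && stats::runif(1) < config$ambiguity_rate) {
          pick <- sample.int(length(available_codes), 1)
          syn <- c(syn, available_codes[pick])
          available_codes <- available_codes[-pick]
        } else if (!is.null(e$code)) {
          syn <- c(syn, e$code)
          available_codes <- c(available_codes, e$code)
        }
        rows[[i]] <- data.frame(entry_id = ids[i], preferred_label = e$label,
                                synonyms = paste(syn, collapse = "|"),
                                stringsAsFactors = FALSE)
      }
      as_lexicon(do.call(rbind, rows), type, paste0("synthetic-", type))
    }

    gp <- build("GP", sizes[["GP"]], function(i) {
      sym <- take_code()
      list(label = sym, synonyms = paste(take_word(), "kinase", sample(1:9, 1)),
           code = NULL)
    })
    ds <- build("DS", sizes[["DS"]], function(i) {
      head_word <- take_word()
      kind <- sample(c("syndrome", "disease"), 1)
      list(label = paste(head_word, kind),
           synonyms = paste(head_word, "disorder"), code = take_code())
    })
    cd <- build("CD", sizes[["CD"]], function(i) {
      stem <- take_word()
      list(label = paste0(stem, sample(c("inib", "mab", "olol"), 1)),
           synonyms = character(0), code = take_code())
    })
    og <- build("OG", sizes[["OG"]], function(i) {
      list(label = paste(cap(take_word()), paste0(take_word(), "is")),
           synonyms = character(0), code = NULL)
    })
    list(GP = gp, DS = ds, CD = cd, OG = og)
  })
}

# sentence templates: list(parts = interleaved literals and slot names,
# mapped_pairs = GP/DS/CD pairs when all slots are filled)
SYNTH_TEMPLATES <- list(
  t3 = list(parts = list("", "GP", " is associated with ", "DS",
                         " in patients treated with ", "CD", "."), pairs = 3L),
  t2_gpds = list(parts = list("", "GP", " expression was elevated in ", "DS", "."),
                 pairs = 1L),
  t2_cdds = list(parts = list("Treatment with ", "CD", " reduced ", "DS",
                              " progression."), pairs = 1L),
  t2_cdgp = list(parts = list("Administration of ", "CD", " inhibits ", "GP",
                              " activity."), pairs = 1L),
  t2_og = list(parts = list("Studies in ", "OG", " linked ", "GP", " to ", "DS", "."),
               pairs = 1L),
  t1 = list(parts = list("Expression of ", "GP", " was measured."), pairs = 0L),
  t0 = list(parts = list("The cohort was followed for two years."), pairs = 0L)
)
SLOT_NAMES <- c("GP", "DS", "CD", "OG")

# unfilled-slot fillers; capitalized when sentence-initial
SLOT_FILLERS <- c(GP = "the candidate marker", DS = "the studied condition",
                  CD = "the assigned compound", OG = "the model organism")

#' Generate a synthetic corpus with known truth
#'
#' Builds `n_documents` one-block documents of template sentences. Each
#' document has a topic (one GP, one DS, one CD, one OG entry) reused across
#' its sentences. Surface forms alternate between preferred labels and
#' synonyms; gold mentions are recorded with exact offsets and planted
#' identifiers; true associations are the mapped same-sentence pairs.
#' Deterministic under `config$seed`.
#'
#' @param config a [generator_config()].
#' @param lexicons output of [generate_lexicons()] (regenerated from
#'   `config` when omitted).
#' @return list with `corpus` (block table), `truth`: list of `mentions`
#'   (gold with `entry_id`), `associations` (unique kind/id pairs),
#'   `sentence_pairs` (per-sentence mapped GP/DS/CD slot counts and the
#'   implied pair count).
#' @export
generate_corpus <- function(config, lexicons = generate_lexicons(config)) {
  with_seed(config$seed + 1L, {
    # template mix: choose P(3-slot) and P(2-slot) so the expected number of
    # fully planted pairs per sentence, 3*p3 + p2, equals association_density,
    # keeping a healthy share of 2-slot templates (incl. the organism one)
    density <- config$association_density
    p2 <- min(0.4 * density, (3 - density) / 2, 1)
    p3 <- (density - p2) / 3
    p0 <- max(0, 1 - p3 - p2)
    two_slot <- c("t2_gpds", "t2_cdds", "t2_cdgp", "t2_og")
    zero_slot <- c("t1", "t0")

    # fixed association network: every disease is linked to 2 genes and 2
    # chemicals for the whole corpus, and documents pick their topic from it.
    # Literature has stable association structure (the same disease keeps
    # co-occurring with the same genes/drugs across papers); this is what
    # embedding-based normalization exploits for context disambiguation.
    n_ds <- nrow(lexicons$DS$entries)
    partners_gp <- lapply(seq_len(n_ds), function(i) {
      sample(nrow(lexicons$GP$entries), min(2L, nrow(lexicons$GP$entries)))
    })
    partners_cd <- lapply(seq_len(n_ds), function(i) {
      sample(nrow(lexicons$CD$entries), min(2L, nrow(lexicons$CD$entries)))
    })

    blocks <- vector("list", config$n_documents)
    mention_rows <- list()
    pair_rows <- list()
    assoc_rows <- list()
    for (d in seq_len(config$n_documents)) {
      doc_id <- sprintf("SYNDOC%04d", d)
      ds_i <- sample(n_ds, 1)
      topic <- list(
        DS = lexicons$DS$entries[ds_i, , drop = FALSE],
        GP = lexicons$GP$entries[sample(partners_gp[[ds_i]], 1), , drop = FALSE],
        CD = lexicons$CD$entries[sample(partners_cd[[ds_i]], 1), , drop = FALSE],
        OG = lexicons$OG$entries[sample(nrow(lexicons$OG$entries), 1), , drop = FALSE]
      )
      introduced <- character(0) # entities already named by preferred label
      block_text <- ""
      offset <- 0L
      for (s in seq_len(config$sentences_per_doc)) {
        u <- stats::runif(1)
        tname <- if (u < p3) "t3" else if (u < p3 + p2) sample(two_slot, 1) else sample(zero_slot, 1)
        tpl <- SYNTH_TEMPLATES[[tname]]
        sent <- ""
        sent_mentions <- list()
        for (part in tpl$parts) {
          if (part %in% SLOT_NAMES) {
            planted <- stats::runif(1) < config$planting_rate
            if (planted) {
              entry <- topic[[part]]
              syns <- entry$synonyms[[1]]
              # first mention in a document introduces the entity by its
              # preferred label (mirroring how abstracts introduce a term
              # before abbreviating it); sentence-initial slots also take the
              # label, since synonyms may start lowercase, which would defeat
              # the uppercase-after-terminator sentence boundary
              use_syn <- nzchar(sent) && entry$entry_id %in% introduced &&
                length(syns) && stats::runif(1) < 0.5
              surface <- if (use_syn) sample(syns, 1) else entry$preferred_label
              if (!use_syn) introduced <- c(introduced, entry$entry_id)
              start <- nchar(sent)
              sent <- paste0(sent, surface)
              sent_mentions[[length(sent_mentions) + 1L]] <- list(
                type = part, start = start, end = nchar(sent),
                surface = surface, entry_id = entry$entry_id
              )
            } else {
              filler <- SLOT_FILLERS[[part]]
              if (!nzchar(sent)) {
                filler <- paste0(toupper(substr(filler, 1, 1)),
                                 substr(filler, 2, nchar(filler)))
              }
              sent <- paste0(sent, filler)
            }
          } else {
            sent <- paste0(sent, part)
          }
        }
        # spurious mention noise: an extra lexicon surface absent from gold
        if (stats::runif(1) < config$noise_rate) {
          tt <- sample(GROUNDABLE_TYPES, 1)
          lex <- lexicons[[tt]]
          extra <- lex$entries$preferred_label[sample(nrow(lex$entries), 1)]
          sent <- sub("\\.$", paste0(" (see also ", extra, ")."), sent)
        }
        base <- offset
        for (mn in sent_mentions) {
          mention_rows[[length(mention_rows) + 1L]] <- data.frame(
            doc_id = doc_id, block_index = 0L, sent_index = s - 1L,
            entity_type = mn$type, char_start = mn$start, char_end = mn$end,
            block_start = base + mn$start, block_end = base + mn$end,
            surface = mn$surface, source = "gold", score = NA_real_,
            entry_id = mn$entry_id, stringsAsFactors = FALSE
          )
        }
        types_here <- vapply(sent_mentions, function(m) m$type, "")
        ids_here <- vapply(sent_mentions, function(m) m$entry_id, "")
        gmask <- types_here %in% GROUNDABLE_TYPES
        gcount <- sum(types_here == "GP"); dcount <- sum(types_here == "DS")
        ccount <- sum(types_here == "CD")
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          doc_id = doc_id, block_index = 0L, sent_index = s - 1L,
          g = gcount, d = dcount, c = ccount,
          n_pairs = gcount * dcount + gcount * ccount + dcount * ccount,
          stringsAsFactors = FALSE
        )
        if (sum(gmask) >= 2) {
          gi <- which(gmask)
          for (a in gi[-length(gi)]) for (b in gi[gi > a]) {
            if (types_here[a] == types_here[b] || ids_here[a] == ids_here[b]) next
            swap <- TYPE_ORDER[types_here[a]] > TYPE_ORDER[types_here[b]]
            p <- if (swap) c(b, a) else c(a, b)
            assoc_rows[[length(assoc_rows) + 1L]] <- data.frame(
              kind = pair_kind(types_here[a], types_here[b]),
              entry_id_1 = ids_here[p[1]], entry_id_2 = ids_here[p[2]],
              stringsAsFactors = FALSE
            )
          }
        }
        block_text <- if (nzchar(block_text)) paste0(block_text, " ", sent) else sent
        offset <- nchar(block_text) + 1L # +1 for the joining space
      }
      blocks[[d]] <- data.frame(doc_id = doc_id, block_index = 0L,
                                kind = "paragraph", text = block_text,
                                stringsAsFactors = FALSE)
    }
    corpus <- do.call(rbind, blocks)
    mentions <- if (length(mention_rows)) do.call(rbind, mention_rows) else {
      cbind(empty_mentions(), data.frame(entry_id = character()))
    }
    sentence_pairs <- do.call(rbind, pair_rows)
    assoc <- do.call(rbind, c(
      assoc_rows,
      list(data.frame(kind = character(), entry_id_1 = character(),
                      entry_id_2 = character(), stringsAsFactors = FALSE))
    ))
    assoc <- unique(assoc)
    assoc <- assoc[order(match(assoc$kind, ASSOCIATION_KINDS),
                         assoc$entry_id_1, assoc$entry_id_2), , drop = FALSE]
    rownames(assoc) <- NULL
    rownames(sentence_pairs) <- NULL
    rownames(mentions) <- NULL
    attr(sentence_pairs, "assoc") <- NULL
    list(corpus = corpus,
         truth = list(mentions = mentions, associations = assoc,
                      sentence_pairs = sentence_pairs))
  })
}

#' Generate a token corpus with an interchangeable token pair
#'
#' Produces tokenized sentences in which the two planted tokens appear in
#' identical sampled contexts, so a skip-gram model should place them close
#' together. Used to exercise the embedding-similarity property.
#'
#' @param seed integer seed.
#' @param n_sentences number of sentences (default 300).
#' @param n_filler size of the filler vocabulary (default 80).
#' @return list with `sentences` (list of token vectors) and `pair`
#'   (character vector of the two interchangeable tokens).
#' @export
generate_interchangeable_corpus <- function(seed, n_sentences = 300L,
                                            n_filler = 80L) {
  with_seed(seed, {
    filler <- make_word_pool(n_filler)
    pair <- c("zetorin", "qimodan")
    # fixed context templates with one hole, built from the filler vocabulary
    templates <- lapply(seq_len(8L), function(i) {
      k <- sample(5:8, 1)
      ctx <- sample(filler[seq_len(20)], k, replace = FALSE)
      hole <- sample(seq_len(k + 1L) - 1L, 1)
      list(ctx = ctx, hole = hole)
    })
    sentences <- lapply(seq_len(n_sentences), function(i) {
      tpl <- templates[[sample(length(templates), 1)]]
      tok <- sample(pair, 1)
      out <- append(tpl$ctx, tok, after = tpl$hole)
      # light variation outside the window-relevant context
      if (stats::runif(1) < 0.5) out <- c(out, sample(filler, 2))
      out
    })
    list(sentences = sentences, pair = pair)
  })
}

#' Write a synthetic bundle to disk
#'
#' Writes the corpus (blocks format), the four lexicons, the gold standoff
#' TSV (with a separate `entry_id` truth column in `truth_ids.tsv`), and the
#' true association set, in the formats the other modules read.
#'
#' @param config a [generator_config()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_bundle <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lex <- generate_lexicons(config)
  gen <- generate_corpus(config, lex)
  write_documents(gen$corpus, file.path(dir, "corpus.ndjson"))
  for (tt in names(lex)) {
    write_lexicon(lex[[tt]], file.path(dir, paste0("lexicon_", tt, ".tsv")))
  }
  write_gold(gen$truth$mentions, file.path(dir, "gold.tsv"))
  utils::write.table(
    gen$truth$mentions[, c("doc_id", "block_index", "block_start", "block_end",
                           "entity_type", "surface", "entry_id")],
    file.path(dir, "truth_ids.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(gen$truth$associations, file.path(dir, "true_associations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
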