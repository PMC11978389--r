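# Co-occurrence extraction, aggregation, ranking.

grounded <- function(doc, sent, type, id, start, surface = "x") {
  m <- make_mention(doc, type, start, start + nchar(surface), surface,
                    sent_index = sent)
  m$entry_id <- id; m$method <- "exact"; m$confidence <- 1
  m
}

test_that("pairs form only across distinct groundable types", {
  g <- bind_mentions(
    grounded("d1", 0L, "GP", "G:1", 0L),
    grounded("d1", 0L, "DS", "D:1", 5L)
  )
  cooc <- extract_cooccurrences(g)
  expect_equal(nrow(cooc), 1L)
  expect_equal(cooc$kind, "GP-DS")
  expect_equal(cooc$entry_id_1, "G:1")
  expect_equal(cooc$entry_id_2, "D:1")

  # 2 GP + 1 DS + 1 CD -> 2 GP-DS, 2 GP-CD, 1 DS-CD
  g2 <- bind_mentions(
    grounded("d1", 0L, "GP", "G:1", 0L), grounded("d1", 0L, "GP", "G:2", 6L),
    grounded("d1", 0L, "DS", "D:1", 12L), grounded("d1", 0L, "CD", "C:1", 20L)
  )
  cooc2 <- extract_cooccurrences(g2)
  expect_equal(nrow(cooc2), 5L)
  expect_equal(as.vector(table(cooc2$kind)[c("GP-DS", "GP-CD", "DS-CD")]),
               c(2L, 2L, 1L))

  # single mention, same-type pairs, OG and UNMAPPED involvement -> nothing
  expect_equal(nrow(extract_cooccurrences(g[1, ])), 0L)
  gg <- bind_mentions(grounded("d1", 0L, "GP", "G:1", 0L),
                      grounded("d1", 0L, "GP", "G:2", 6L))
  expect_equal(nrow(extract_cooccurrences(gg)), 0L)
  og <- bind_mentions(grounded("d1", 0L, "GP", "G:1", 0L),
                      grounded("d1", 0L, "OG", "O:1", 6L))
  expect_equal(nrow(extract_cooccurrences(og)), 0L)
  un <- bind_mentions(grounded("d1", 0L, "GP", "G:1", 0L),
                      grounded("d1", 0L, "DS", "UNMAPPED", 6L))
  un$method[2] <- "unmapped"
  expect_equal(nrow(extract_cooccurrences(un)), 0L)
  # both endpoints grounding to one id are excluded
  same <- bind_mentions(grounded("d1", 0L, "GP", "X:1", 0L),
                        grounded("d1", 0L, "DS", "X:1", 6L))
  expect_equal(nrow(extract_cooccurrences(same)), 0L)
})

test_that("pair counts obey g*d + g*c + d*c per sentence on random inputs", {
  set.seed(404)
  for (rep in 1:100) {
    n <- sample(0:6, 1)
    if (n == 0) next
    types <- sample(c("GP", "DS", "CD"), n, replace = TRUE)
    rows <- lapply(seq_len(n), function(i) {
      grounded("d1", 0L, types[i], paste0(types[i], ":", i), i * 10L)
    })
    g <- do.call(rbind, rows)
    got <- nrow(extract_cooccurrences(g))
    cnt <- table(factor(types, c("GP", "DS", "CD")))
    expect_equal(got, unname(cnt["GP"] * cnt["DS"] + cnt["GP"] * cnt["CD"] +
                               cnt["DS"] * cnt["CD"]))
  }
})

test_that("aggregation groups by canonical pair and conserves evidence", {
  cooc <- rbind(
    data.frame(doc_id = "d1", block_index = 0L, sent_index = 0L, kind = "GP-DS",
               entry_id_1 = "G:1", entry_id_2 = "D:1", evidence_text = NA),
    data.frame(doc_id = "d1", block_index = 0L, sent_index = 1L, kind = "GP-DS",
               entry_id_1 = "G:1", entry_id_2 = "D:1", evidence_text = NA),
    data.frame(doc_id = "d2", block_index = 0L, sent_index = 0L, kind = "DS-CD",
               entry_id_1 = "D:1", entry_id_2 = "C:1", evidence_text = NA)
  )
  rec <- aggregate_associations(cooc)
  expect_equal(nrow(rec), 2L)
  gp <- rec[rec$kind == "GP-DS", ]
  expect_equal(gp$evidence_count, 2L)
  expect_equal(gp$document_count, 1L)
  expect_equal(sum(rec$evidence_count), nrow(cooc))
  expect_true(all(rec$evidence_count >= rec$document_count))
  expect_equal(nrow(aggregate_associations(cooc[0, ])), 0L)
})

test_that("aggregation equals a brute-force group-by on random streams", {
  set.seed(505)
  for (rep in 1:30) {
    n <- sample(1:40, 1)
    cooc <- data.frame(
      doc_id = sample(c("d1", "d2", "d3"), n, replace = TRUE),
      block_index = 0L, sent_index = sample(0:3, n, replace = TRUE),
      kind = "GP-DS",
      entry_id_1 = sample(c("G:1", "G:2"), n, replace = TRUE),
      entry_id_2 = sample(c("D:1", "D:2"), n, replace = TRUE),
      evidence_text = NA, stringsAsFactors = FALSE
    )
    rec <- aggregate_associations(cooc)
    key <- paste(cooc$kind, cooc$entry_id_1, cooc$entry_id_2)
    for (i in seq_len(nrow(rec))) {
      k <- paste(rec$kind[i], rec$entry_id_1[i], rec$entry_id_2[i])
      expect_equal(rec$evidence_count[i], sum(key == k))
      expect_equal(rec$document_count[i], length(unique(cooc$doc_id[key == k])))
    }
    expect_equal(sum(rec$evidence_count), n)
  }
})

test_that("ranking scores follow log10(1 + count) * clamped cosine", {
  sents <- c(replicate(30, c("genea", "links", "diseaseb", "strongly"), simplify = FALSE),
             replicate(30, c("genec", "unrelated", "noise", "here"), simplify = FALSE))
  model <- train_embeddings(sents, embedding_params(dim = 16, seed = 6))
  lex <- list(GP = make_lexicon("GP", entry("G:1", "genea"), entry("G:2", "genec")),
              DS = make_lexicon("DS", entry("D:1", "diseaseb")))
  rec <- data.frame(kind = c("GP-DS", "GP-DS"),
                    entry_id_1 = c("G:1", "G:2"), entry_id_2 = c("D:1", "D:1"),
                    evidence_count = c(9L, 9L), document_count = c(2L, 2L),
                    stringsAsFactors = FALSE)
  ranked <- rank_associations(rec, model, lex)
  # hand check: score = log10(1 + 9) * max(0, cos) = 1 * cos
  v <- function(tok) model$vectors[tok, ]
  cos1 <- max(0, cosine_similarity(v("genea"), v("diseaseb")))
  expect_equal(ranked$score[ranked$entry_id_1 == "G:1"], cos1)
  expect_true(all(ranked$score_defined))
  # monotone in evidence count at fixed similarity
  rec2 <- rec[1, ]; rec2$evidence_count <- 99L
  r2 <- rank_associations(rbind(rec[1, ], rec2), model, lex)
  expect_equal(r2$entry_id_1[1], "G:1")
  expect_gt(max(r2$score), min(r2$score) * 1.9) # log10(100)/log10(10) = 2
  # absent phrase vector flags score 0
  lex_missing <- list(GP = make_lexicon("GP", entry("G:9", "neverseen")),
                      DS = lex$DS)
  rec3 <- data.frame(kind = "GP-DS", entry_id_1 = "G:9", entry_id_2 = "D:1",
                     evidence_count = 5L, document_count = 1L)
  r3 <- rank_associations(rec3, model, lex_missing)
  expect_equal(r3$score, 0)
  expect_false(r3$score_defined)
})

test_that("noise-free synthetic run recovers the planted association set exactly", {
  cfg <- generator_config(seed = 17, n_documents = 40)
  lexs <- generate_lexicons(cfg)
  gen <- generate_corpus(cfg, lexs)
  sent <- split_sentences(gen$corpus)
  tags <- tag_corpus(compile_matcher(lexs), sent)
  res <- ground_corpus(tags, lexs[c("GP", "DS", "CD")], sentences = sent)
  cooc <- extract_cooccurrences(res$groundings, sent)
  got <- unique(cooc[, c("kind", "entry_id_1", "entry_id_2")])
  want <- gen$truth$associations
  expect_setequal(paste(got$kind, got$entry_id_1, got$entry_id_2),
                  paste(want$kind, want$entry_id_1, want$entry_id_2))
  # per-sentence counts match the generator's pair bookkeeping
  key <- paste(cooc$doc_id, cooc$sent_index)
  sp <- gen$truth$sentence_pairs
  for (i in which(sp$n_pairs > 0)) {
    expect_equal(sum(key == paste(sp$doc_id[i], sp$sent_index[i])), sp$n_pairs[i])
  }
  expect_equal(nrow(cooc), sum(sp$n_pairs))
})
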