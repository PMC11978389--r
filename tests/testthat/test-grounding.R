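# Grounding cascade: tier order, confidences, conservation, tau monotonicity.

ds_lexicon <- function() {
  make_lexicon("DS",
    entry("EFO:1", "type 2 diabetes", "T2D|diabetes type 2"),
    entry("EFO:2", "breast cancer", "mammary cancer"),
    entry("EFO:3", "asthma"))
}

mention_of <- function(surface, type = "DS") {
  m <- make_mention("d1", type, 0L, nchar(surface), surface)
  m
}

test_that("exact tier grounds preferred labels with confidence 1", {
  g <- ground_mention(mention_of("type 2 diabetes"), ds_lexicon())
  expect_equal(g$entry_id, "EFO:1")
  expect_equal(g$method, "exact")
  expect_equal(g$confidence, 1.0)
  # case and spacing are normalized first
  g2 <- ground_mention(mention_of("Type 2  Diabetes"), ds_lexicon())
  expect_equal(g2$entry_id, "EFO:1")
})

test_that("synonym tier grounds unambiguous synonyms at 0.9", {
  g <- ground_mention(mention_of("T2D"), ds_lexicon())
  expect_equal(g$entry_id, "EFO:1")
  expect_equal(g$method, "synonym")
  expect_equal(g$confidence, 0.9)
})

test_that("fuzzy tier needs a unique term within the edit distance", {
  g <- ground_mention(mention_of("asthmaa"), ds_lexicon())
  expect_equal(g$entry_id, "EFO:3")
  expect_equal(g$method, "fuzzy")
  expect_equal(g$confidence, 0.7)
  # two terms at distance 1 -> ambiguous, tier passes, UNMAPPED without model
  lex2 <- make_lexicon("DS", entry("X:1", "grax"), entry("X:2", "gras"))
  g2 <- ground_mention(mention_of("grap"), lex2)
  expect_equal(g2$entry_id, "UNMAPPED")
})

test_that("unmappable surfaces come back UNMAPPED with confidence 0", {
  g <- ground_mention(mention_of("completely unrelated thing"), ds_lexicon())
  expect_equal(g$entry_id, "UNMAPPED")
  expect_equal(g$method, "unmapped")
  expect_equal(g$confidence, 0)
  # type mismatch is a validation error
  expect_error(ground_mention(mention_of("asthma", type = "CD"), ds_lexicon()),
               "does not match")
})

test_that("cascade tiers are individually switchable", {
  pol_no_exact <- grounding_policy(cascade = c("synonym", "fuzzy"))
  g <- ground_mention(mention_of("type 2 diabetes"), ds_lexicon(), policy = pol_no_exact)
  # preferred labels are also in the term index, so the synonym tier fires
  expect_equal(g$method, "synonym")
  pol_fuzzy_only <- grounding_policy(cascade = "fuzzy")
  g2 <- ground_mention(mention_of("T2D"), ds_lexicon(), policy = pol_fuzzy_only)
  expect_equal(g2$entry_id, "UNMAPPED") # T2D is distance-2+ from every term
})

test_that("embedding tier accepts iff similarity reaches tau; raising tau never maps more", {
  # corpus in which "glucohol" shares contexts with the label token "asthma"
  sents <- c(replicate(40, c("patients", "with", "asthma", "wheeze", "daily"), simplify = FALSE),
             replicate(40, c("patients", "with", "glucohol", "wheeze", "daily"), simplify = FALSE),
             replicate(40, c("random", "filler", "words", "about", "nothing"), simplify = FALSE))
  # subsampling off: this miniature corpus has so few distinct tokens that
  # every token would sit above the frequency threshold
  model <- train_embeddings(sents, embedding_params(dim = 32, seed = 4, subsample = 0))
  lex <- make_lexicon("DS", entry("EFO:3", "asthma"))
  pol <- function(tau) grounding_policy(tau = tau, cascade = "embedding")
  g_low <- ground_mention(mention_of("glucohol"), lex, model, pol(0.05))
  expect_equal(g_low$entry_id, "EFO:3")
  expect_equal(g_low$method, "embedding")
  expect_gte(g_low$confidence, 0.05)
  g_high <- ground_mention(mention_of("glucohol"), lex, model, pol(0.999))
  expect_equal(g_high$entry_id, "UNMAPPED")

  # monotone tau on a whole corpus run
  cfg <- generator_config(seed = 21, n_documents = 15)
  lexs <- generate_lexicons(cfg)
  gen <- generate_corpus(cfg, lexs)
  sent <- split_sentences(gen$corpus)
  tags <- tag_corpus(compile_matcher(lexs), sent)
  mod <- train_embeddings(tokenize(sent$text), embedding_params(dim = 32, epochs = 2, seed = 21))
  mapped_at <- vapply(c(0.1, 0.5, 0.9), function(tau) {
    res <- ground_corpus(tags, lexs[c("GP", "DS", "CD")], mod,
                         grounding_policy(tau = tau), sent)
    sum(res$groundings$entry_id != "UNMAPPED")
  }, 0)
  expect_true(all(diff(mapped_at) <= 0))
})

test_that("ground_corpus conserves mentions and exports the failed list", {
  lex <- list(DS = ds_lexicon(),
              GP = make_lexicon("GP", entry("G:1", "TP53")),
              CD = make_lexicon("CD", entry("C:1", "aspirin")))
  corpus <- make_corpus("TP53 and quuxozine in type 2 diabetes.")
  sentences <- split_sentences(corpus)
  mentions <- bind_mentions(
    make_mention("d1", "GP", 0L, 4L, "TP53"),
    make_mention("d1", "CD", 9L, 18L, "quuxozine"), # will not ground
    make_mention("d1", "DS", 22L, 37L, "type 2 diabetes"),
    make_mention("d1", "OG", 0L, 4L, "TP53") # OG passes through, not grounded
  )
  res <- ground_corpus(mentions, lex, sentences = sentences)
  expect_equal(nrow(res$groundings), 3L) # OG excluded
  expect_equal(sum(res$groundings$entry_id != "UNMAPPED") + nrow(res$failed), 3L)
  expect_equal(res$failed$surface, "quuxozine")
  expect_equal(res$failed$sentence_text, corpus$text)

  f <- withr::local_tempfile()
  write_failed(res$failed, f)
  rec <- jsonlite::fromJSON(readLines(f)[1])
  expect_equal(rec$exact, "quuxozine")
  expect_equal(rec$sentence_text, corpus$text)

  # all-exact corpus: failed list is empty
  ok <- ground_corpus(mentions[c(1, 3), ], lex, sentences = sentences)
  expect_equal(nrow(ok$failed), 0L)
  # missing lexicon for a groundable type is an error
  expect_error(ground_corpus(mentions, lex["DS"], sentences = sentences),
               "no lexicon")
})

test_that("confidence honors the tier ordering exact >= synonym >= fuzzy", {
  lex <- ds_lexicon()
  g_ex <- ground_mention(mention_of("asthma"), lex)
  g_syn <- ground_mention(mention_of("T2D"), lex)
  g_fz <- ground_mention(mention_of("asthmaa"), lex)
  expect_true(g_ex$confidence >= g_syn$confidence)
  expect_true(g_syn$confidence >= g_fz$confidence)
})

test_that("context tier recovers planted ids for ambiguous synonyms (>= 80% pooled)", {
  # ambiguity study corpus: two-way shared codes, dense co-mention sentences
  total_ok <- 0L; total_n <- 0L
  for (sd in 1:3) {
    cfg <- generator_config(seed = sd, n_documents = 150, ambiguity_rate = 0.5,
                            association_density = 2.5)
    lexs <- generate_lexicons(cfg)
    gen <- generate_corpus(cfg, lexs)
    sent <- split_sentences(gen$corpus)
    tags <- tag_corpus(compile_matcher(lexs), sent)
    model <- train_embeddings(tokenize(sent$text), embedding_params(seed = sd))
    res <- ground_corpus(tags, lexs[c("GP", "DS", "CD")], model,
                         grounding_policy(), sent)
    g <- res$groundings
    tm <- gen$truth$mentions
    tk <- paste(tm$doc_id, tm$block_start, tm$entity_type)
    truth_id <- tm$entry_id[match(paste(g$doc_id, g$block_start, g$entity_type), tk)]
    amb <- vapply(seq_len(nrow(g)), function(i) {
      length(lexicon_lookup(lexs[[g$entity_type[i]]], g$surface[i])) > 1
    }, TRUE)
    total_ok <- total_ok + sum(g$entry_id[amb] == truth_id[amb])
    total_n <- total_n + sum(amb)
  }
  expect_gt(total_n, 100L)
  expect_gte(total_ok / total_n, 0.8)
})
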