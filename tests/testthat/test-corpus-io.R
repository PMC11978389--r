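# Document ingestion, sentence splitting, gold spans, annotation round-trip.

test_that("plain-format ingestion preserves text and block structure", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("TP53 is mutated.", "", "Second paragraph here."), f)
  docs <- load_documents(f, "plain")
  expect_equal(nrow(docs), 2L)
  expect_equal(docs$block_index, c(0L, 1L))
  expect_equal(docs$text[1], "TP53 is mutated.")
  expect_equal(docs$kind, rep("paragraph", 2))

  single <- withr::local_tempfile(fileext = ".txt")
  writeLines("TP53 is mutated.", single)
  d1 <- load_documents(single, "plain")
  expect_equal(nrow(d1), 1L)
  expect_equal(d1$text, "TP53 is mutated.")

  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), empty)
  expect_error(load_documents(empty, "plain"), "zero blocks")
  expect_error(load_documents(file.path(tempdir(), "nope-missing.txt")),
               class = "litmine_input_error")
})

test_that("blocks format carries kind and round-trips through write_documents", {
  f <- withr::local_tempfile()
  writeLines(c(
    '{"doc_id":"d1","kind":"title","text":"A title"}',
    '{"doc_id":"d1","kind":"table","text":"Gene\\tDisease\\nTP53\\tcancer"}'
  ), f)
  docs <- load_documents(f, "blocks")
  expect_equal(docs$kind, c("title", "table"))
  expect_equal(docs$block_index, c(0L, 1L))
  expect_equal(docs$text[2], "Gene\tDisease\nTP53\tcancer")

  out <- withr::local_tempfile()
  write_documents(docs, out)
  expect_identical(load_documents(out, "blocks"), docs)
})

test_that("sentence splitting matches offsets, protects abbreviations, splits table rows", {
  corpus <- make_corpus("TP53 is mutated. It drives cancer.")
  s <- split_sentences(corpus)
  expect_equal(s$char_start, c(0L, 17L))
  expect_equal(s$char_end, c(16L, 34L))
  expect_equal(s$text, c("TP53 is mutated.", "It drives cancer."))

  # species abbreviation: no break before a lowercase word
  s2 <- split_sentences(make_corpus("E. coli causes disease."))
  expect_equal(nrow(s2), 1L)
  # protected list entries
  s3 <- split_sentences(make_corpus("As shown by Smith et al. The result held. See Fig. 2 for details."))
  expect_equal(nrow(s3), 2L)
  expect_match(s3$text[1], "^As shown by Smith et al\\. The result held\\.$")

  tab <- make_corpus("Gene\tDisease\nTP53\tcancer", kind = "table")
  st <- split_sentences(tab)
  expect_equal(nrow(st), 2L)
  expect_equal(st$text, c("Gene\tDisease", "TP53\tcancer"))

  # whitespace-only block yields zero sentences
  expect_equal(nrow(split_sentences(make_corpus("   \n  "))), 0L)
})

test_that("sentence spans are disjoint, slice-consistent and idempotent", {
  texts <- c(
    "One sentence only",
    "First! Second? Third sentence ends. 4 follows with digits.",
    "Dr. Smith measured TP53 vs. control. No change seen.",
    "Trailing spaces here.   Next one.  "
  )
  corpus <- make_corpus(texts)
  s <- split_sentences(corpus)
  for (d in unique(s$doc_id)) {
    sd <- s[s$doc_id == d, ]
    blk <- corpus$text[corpus$doc_id == d]
    # text equals the slice
    expect_equal(sd$text, substring(blk, sd$char_start + 1, sd$char_end))
    # pairwise disjoint and ordered
    if (nrow(sd) > 1) {
      expect_true(all(sd$char_start[-1] >= sd$char_end[-nrow(sd)]))
    }
    # idempotence: re-splitting each sentence yields the sentence itself
    for (txt in sd$text) {
      again <- split_sentences(make_corpus(txt))
      expect_equal(again$text, txt)
    }
  }
})

test_that("read_gold validates offsets, types and surface against the corpus", {
  corpus <- make_corpus("TP53 is mutated.")
  sentences <- split_sentences(corpus)
  f <- withr::local_tempfile()
  writeLines(c("doc_id\tblock_index\tchar_start\tchar_end\tentity_type\tsurface",
               "d1\t0\t0\t4\tGP\tTP53"), f)
  gold <- read_gold(f, corpus, sentences)
  expect_equal(nrow(gold), 1L)
  expect_equal(gold$entity_type, "GP")
  expect_equal(gold$block_start, 0L)
  expect_equal(gold$block_end, 4L)
  expect_equal(gold$sent_index, 0L)

  bad_surface <- withr::local_tempfile()
  writeLines(c("doc_id\tblock_index\tchar_start\tchar_end\tentity_type\tsurface",
               "d1\t0\t0\t4\tGP\tTP5X"), bad_surface)
  expect_error(read_gold(bad_surface, corpus), "row 1")

  bad_offset <- withr::local_tempfile()
  writeLines(c("doc_id\tblock_index\tchar_start\tchar_end\tentity_type\tsurface",
               "d1\t0\t10\t99\tGP\tTP53"), bad_offset)
  expect_error(read_gold(bad_offset, corpus), "outside block")

  bad_type <- withr::local_tempfile()
  writeLines(c("doc_id\tblock_index\tchar_start\tchar_end\tentity_type\tsurface",
               "d1\t0\t0\t4\tXX\tTP53"), bad_type)
  expect_error(read_gold(bad_type, corpus), "entity type")

  empty <- withr::local_tempfile()
  writeLines("doc_id\tblock_index\tchar_start\tchar_end\tentity_type\tsurface", empty)
  expect_equal(nrow(read_gold(empty, corpus)), 0L)
})

test_that("annotations round-trip and clip context at sentence boundaries", {
  corpus <- make_corpus("TP53 is mutated in many aggressive human cancers.")
  sentences <- split_sentences(corpus)
  m <- make_mention("d1", "GP", 0L, 4L, "TP53")
  m$entry_id <- "ENSG:1"; m$method <- "exact"; m$confidence <- 1
  f <- withr::local_tempfile()
  write_annotations(m, sentences, f)
  rec <- jsonlite::fromJSON(readLines(f)[1])
  expect_equal(rec$prefix, "")
  expect_equal(rec$postfix, " is mutated in many ")
  expect_equal(nchar(rec$postfix), 20L)
  expect_equal(rec$exact, "TP53")
  expect_equal(rec$id, "ENSG:1")

  back <- read_annotations(f, sentences)
  expect_equal(back$surface, m$surface)
  expect_equal(back$entity_type, m$entity_type)
  expect_equal(back$char_start, m$char_start)
  expect_equal(back$char_end, m$char_end)
  expect_equal(back$block_start, m$block_start)
  expect_equal(back$entry_id, m$entry_id)
  expect_equal(back$confidence, m$confidence)

  # empty annotation set is valid and reads back empty
  f2 <- withr::local_tempfile()
  write_annotations(m[0, ], sentences, f2)
  expect_equal(nrow(read_annotations(f2, sentences)), 0L)
})

test_that("write/read round-trip over a whole synthetic tagging run", {
  cfg <- generator_config(seed = 5, n_documents = 10)
  lex <- generate_lexicons(cfg)
  gen <- generate_corpus(cfg, lex)
  sentences <- split_sentences(gen$corpus)
  mentions <- tag_corpus(compile_matcher(lex), sentences)
  f <- withr::local_tempfile()
  write_annotations(mentions, sentences, f)
  back <- read_annotations(f, sentences)
  cols <- c("doc_id", "block_index", "sent_index", "entity_type",
            "char_start", "char_end", "block_start", "block_end", "surface")
  expect_equal(back[, cols], mentions[, cols], ignore_attr = TRUE)
})
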