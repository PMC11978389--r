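# Strict/partial span matching, P/R/F1 arithmetic, overlap report, kappa.

test_that("strict and partial matching follow the span definitions", {
  g <- make_mention("d1", "GP", 0L, 4L, "TP53")
  p_same <- make_mention("d1", "GP", 0L, 4L, "TP53")
  m <- match_mentions(g, p_same, "strict")
  expect_equal(m[, c("tp", "fp", "fn")], data.frame(tp = 1L, fp = 0L, fn = 0L),
               ignore_attr = TRUE)

  p_wide <- make_mention("d1", "GP", 0L, 6L, "TP53 i")
  ms <- match_mentions(g, p_wide, "strict")
  expect_equal(unlist(ms[, c("tp", "fp", "fn")]), c(tp = 0L, fp = 1L, fn = 1L))
  mp <- match_mentions(g, p_wide, "partial")
  expect_equal(unlist(mp[, c("tp", "fp", "fn")]), c(tp = 1L, fp = 0L, fn = 0L))

  # empty gold: everything predicted is a false positive in both modes
  preds <- bind_mentions(make_mention("d1", "DS", 0L, 3L, "foo"),
                         make_mention("d1", "DS", 5L, 8L, "bar"),
                         make_mention("d1", "DS", 9L, 12L, "baz"))
  for (mode in c("strict", "partial")) {
    mm <- match_mentions(preds[0, ], preds, mode)
    expect_equal(unlist(mm[, c("tp", "fp", "fn")]), c(tp = 0L, fp = 3L, fn = 0L))
  }

  # each gold mention absorbs at most one prediction
  dup <- bind_mentions(p_same, p_same)
  md <- match_mentions(g, dup, "strict")
  expect_equal(unlist(md[, c("tp", "fp", "fn")]), c(tp = 1L, fp = 1L, fn = 0L))
})

test_that("strict matching equals the tuple-intersection oracle on random sets", {
  set.seed(101)
  for (rep in 1:100) {
    gold <- random_mentions(sample(0:8, 1))
    pred <- random_mentions(sample(0:8, 1))
    got <- match_mentions(gold, pred, "strict")
    for (tt in unique(c(gold$entity_type, pred$entity_type))) {
      gk <- with(gold[gold$entity_type == tt, ],
                 paste(doc_id, block_index, block_start, block_end))
      pk <- with(pred[pred$entity_type == tt, ],
                 paste(doc_id, block_index, block_start, block_end))
      # multiset intersection size
      tp_oracle <- sum(pmin(table(factor(gk, levels = unique(c(gk, pk)))),
                            table(factor(pk, levels = unique(c(gk, pk))))))
      row <- got[got$entity_type == tt, ]
      expect_equal(row$tp, tp_oracle)
      expect_equal(row$tp + row$fn, length(gk))
      expect_equal(row$tp + row$fp, length(pk))
    }
  }
})

test_that("partial true positives never fall below strict true positives", {
  set.seed(202)
  for (rep in 1:50) {
    gold <- random_mentions(sample(1:8, 1))
    pred <- random_mentions(sample(1:8, 1))
    s <- match_mentions(gold, pred, "strict")
    p <- match_mentions(gold, pred, "partial")
    key <- function(x) x$tp[match(s$entity_type, x$entity_type)]
    expect_true(all(key(p) >= s$tp, na.rm = TRUE))
  }
})

test_that("score computes P/R/F1 with the degenerate-input convention", {
  counts <- data.frame(entity_type = "GP", mode = "strict",
                       tp = 9L, fp = 1L, fn = 1L)
  sc <- score(counts)
  expect_equal(sc$precision, 0.9)
  expect_equal(sc$recall, 0.9)
  expect_equal(sc$f1, 0.9)

  zero <- score(data.frame(entity_type = "GP", mode = "strict",
                           tp = 0L, fp = 0L, fn = 0L))
  expect_equal(zero$precision, 0)
  expect_equal(zero$recall, 0)
  expect_equal(zero$f1, 0)
})

test_that("F1 from rounded precision/recall reproduces benchmark-table arithmetic", {
  # harmonic mean of printed two-decimal P/R, rounded half away from zero
  expect_equal(f1_from_pr(0.53, 0.34), 0.41)
  expect_equal(f1_from_pr(0.48, 0.74), 0.58)
  expect_equal(f1_from_pr(0.90, 0.80), 0.85)
  expect_equal(f1_from_pr(0, 0), 0)
  expect_equal(f1_from_pr(0.53, 0.34, digits = Inf), 2 * 0.53 * 0.34 / 0.87)
})

test_that("overlap report decomposes into shared / system-only / gold-only", {
  gold <- bind_mentions(make_mention("d1", "GP", 0L, 4L, "TP53"),
                        make_mention("d1", "DS", 8L, 14L, "cancer"))
  sys_a <- gold # identical to gold
  sys_b <- make_mention("d1", "GP", 20L, 24L, "EGFR") # disjoint
  rep <- overlap_report(gold, sys_a, sys_b, names = c("dict", "dl"))
  a <- rep[rep$system == "dict", ]
  expect_equal(sum(a$shared), 2L)
  expect_equal(sum(a$system_only), 0L)
  expect_equal(sum(a$gold_only), 0L)
  b <- rep[rep$system == "dl", ]
  expect_equal(sum(b$shared), 0L)
  expect_equal(sum(b$system_only), 1L)
  # gold_only + shared equals the gold count per type for every system
  for (sys in unique(rep$system)) {
    r <- rep[rep$system == sys, ]
    for (tt in unique(gold$entity_type)) {
      rr <- r[r$entity_type == tt, ]
      expect_equal(rr$shared + rr$gold_only, sum(gold$entity_type == tt))
    }
  }
})

test_that("kappa matches hand-worked examples and handles edge cases", {
  expect_equal(cohen_kappa(c("A", "B", "A"), c("A", "B", "A"))$kappa, 1)
  k <- cohen_kappa(c("A", "A", "B", "B"), c("A", "B", "A", "B"))
  expect_equal(k$p_o, 0.5)
  expect_equal(k$p_e, 0.5)
  expect_equal(k$kappa, 0)
  # one annotator constant, the other mixed: kappa collapses to 0
  k2 <- cohen_kappa(rep("A", 4), c("A", "A", "B", "B"))
  expect_equal(k2$kappa, 0)
  # both constant on the same label: undefined, flagged
  k3 <- cohen_kappa(rep("A", 3), rep("A", 3))
  expect_true(k3$undefined)
  expect_equal(k3$kappa, 1)
  expect_error(cohen_kappa(c("A"), c("A", "B")), "length")
  expect_error(cohen_kappa(character(0), character(0)), "non-empty")
})

test_that("kappa equals the confusion-matrix brute force on random labels", {
  set.seed(303)
  classes <- c("AlteredExpression", "GeneticVariation", "RegulatoryModification",
               "Any", "NA", "No")
  for (rep in 1:100) {
    n <- sample(5:40, 1)
    a <- sample(classes, n, replace = TRUE)
    b <- sample(classes, n, replace = TRUE)
    got <- cohen_kappa(a, b)
    cm <- table(factor(a, classes), factor(b, classes)) / n
    p_o <- sum(diag(cm))
    p_e <- sum(rowSums(cm) * colSums(cm))
    expect_equal(got$p_o, p_o)
    expect_equal(got$p_e, p_e)
    if (p_e < 1) expect_equal(got$kappa, (p_o - p_e) / (1 - p_e))
  }
})
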