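test_that("word-class ratios follow both denominators", {
  tok <- make_tokens(8)
  tok$pos <- c("noun", "noun", "verb", "adjective", "other", "other",
               "other", "other")
  tok$is_stop <- FALSE
  tr <- aligned_transcript(tok)
  r <- word_class_ratios(tr)
  expect_equal(unname(r["lexsem__noun_ratio__all"]), 0.25)
  expect_equal(unname(r["lexsem__noun_ratio__content"]), 0.5)

  tok$pos <- "noun"
  r2 <- word_class_ratios(aligned_transcript(tok))
  expect_equal(unname(r2["lexsem__noun_ratio__all"]), 1)
  expect_equal(unname(r2["lexsem__noun_ratio__content"]), 1)

  # no content words -> content-relative ratios are NA markers
  tok$pos <- "other"
  r3 <- word_class_ratios(aligned_transcript(tok))
  expect_true(all(is.na(r3[grepl("__content$", names(r3))])))
  expect_true(all(r3[grepl("__all$", names(r3))] == 0))

  # hand-count oracle on a random POS sequence; permutation invariance
  set.seed(10)
  tok <- make_tokens(40, seed = 10)
  tr <- aligned_transcript(tok)
  r4 <- word_class_ratios(tr)
  expect_equal(unname(r4["lexsem__verb_ratio__all"]),
               sum(tok$pos == "verb") / 40)
  perm <- tok[sample(40), ]
  perm <- perm[order(perm$onset_s), ]  # re-sort times, POS multiset identical
  expect_equal(word_class_ratios(aligned_transcript(perm)), r4)
})

test_that("granularity is min hypernym depth; BFS equals path enumeration", {
  g <- toy_chain_graph()
  expect_equal(granularity("entity", g), 0)
  expect_lt(granularity("animal", g), granularity("dog", g))
  expect_lt(granularity("dog", g), granularity("bulldog", g))
  expect_true(is.na(granularity("xylophone", g)))

  # two hypernym paths of different lengths -> the shorter one wins
  g2 <- hypernym_graph(data.frame(
    child = c("a", "b", "c", "d", "x", "x"),
    parent = c("entity", "a", "b", "c", "a", "d")))
  expect_equal(granularity("x", g2), 2)  # via a, not via d (length 5)

  for (s in 1:20) {
    g3 <- random_dag(sample(5:50, 1), seed = s)
    for (node in sample(g3$nodes, min(8, length(g3$nodes)))) {
      expect_equal(granularity(node, g3), enumerate_depth(node, g3))
    }
  }
})

test_that("granularity features bin against the total word count", {
  g <- toy_chain_graph()
  tok <- make_tokens(8, words = c("dog", "cat", "bulldog", "unknownword"))
  tr <- aligned_transcript(tok)
  f <- granularity_features(tr, g, bins = c(2, 3))
  # 8 tokens: dog(2) cat(2) x2, bulldog(3) x2, OOV x2
  expect_equal(unname(f["lexsem__granularity_prop_low"]), 4 / 8)
  expect_equal(unname(f["lexsem__granularity_prop_high"]), 2 / 8)
  expect_equal(unname(f["lexsem__granularity_prop_intermediate"]), 0)
  # proportions sum to the in-vocabulary fraction
  expect_equal(sum(f[grepl("prop", names(f))]), 6 / 8)
  expect_equal(unname(f["lexsem__granularity__mean"]), mean(c(2, 2, 3, 2, 2, 3)))
})

test_that("semantic variability equals the direct cosine oracle", {
  words <- c("A", "B", "C", "D", "E")
  emb <- make_embeddings(words)
  set.seed(6)
  tok <- make_tokens(10, words = sample(words, 10, replace = TRUE))
  tok$pos <- "noun"; tok$is_stop <- FALSE
  tr <- aligned_transcript(tok)
  v <- semantic_variability(tr, emb, "content")
  # independent loop over the explicit cosine formula
  vecs <- emb$vectors[tok$token, ]
  d <- sapply(1:9, function(i) {
    a <- vecs[i, ]; b <- vecs[i + 1, ]
    1 - sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  })
  expect_equal(v, sum((d - mean(d))^2) / 8, tolerance = 1e-9)
  # scale invariance of the embedding table
  emb2 <- embedding_table(emb$vectors * 37.5)
  expect_equal(semantic_variability(tr, emb2, "content"), v, tolerance = 1e-9)
})

test_that("variability variants collapse repeats and flag degenerate input", {
  words <- c("A", "A", "B")
  tok <- make_tokens(3, words = words)
  tok$pos <- "noun"; tok$is_stop <- FALSE
  tr <- aligned_transcript(tok)
  emb <- make_embeddings(c("A", "B"))
  # [A, A, B] collapses to [A, B]: one distance -> NA marker
  expect_true(is.na(semantic_variability(tr, emb, "nonrep_all")))
  # without collapsing there are two distances -> defined
  expect_false(is.na(semantic_variability(tr, emb, "content")))

  # identical vectors -> all distances zero -> variance exactly 0
  same <- embedding_table(matrix(rep(c(1, 2, 3), 3), 3, byrow = TRUE,
                                 dimnames = list(c("A", "B", "C"), NULL)))
  tok2 <- make_tokens(6, words = c("A", "B", "C"))
  tok2$pos <- "noun"; tok2$is_stop <- FALSE
  expect_identical(semantic_variability(aligned_transcript(tok2), same,
                                        "content"), 0)
})

test_that("embedding table IO round-trips word2vec text format", {
  path <- withr::local_tempfile(fileext = ".vec")
  writeLines(c("3 4",
               "dog 0.1 0.2 0.3 0.4",
               "cat -1 0.5 0 2",
               "jar 1 1 1 1"), path)
  tab <- read_embedding_table(path, "en")
  expect_equal(tab$dim, 4L)
  expect_equal(unname(tab$vectors["cat", ]), c(-1, 0.5, 0, 2))
  expect_error(embedding_table(rbind(dog = c(0, 0))), "zero-norm")
})

test_that("hypernym graph loader validates reachability", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("child\tparent", "animal\tentity", "dog\tanimal"), path)
  g <- read_hypernym_graph(path)
  expect_equal(granularity("dog", g), 2)
  writeLines(c("child\tparent", "a\tb", "b\ta"), path)  # cycle, no root link
  expect_error(read_hypernym_graph(path), "not reachable")
})
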