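test_that("tokenize lowercases, splits on separators and strips punctuation", {
  expect_equal(tokenize("HIV/AIDS"), c("hiv", "aids"))
  expect_equal(tokenize("Guinea-Bissau"), c("guinea", "bissau"))
  expect_equal(tokenize("  Malaria "), "malaria")
  expect_equal(tokenize("Alzheimer's disease"), c("alzheimers", "disease"))
  expect_error(tokenize("''"), class = "incembed_invalid_argument")
  expect_error(tokenize(""), class = "incembed_invalid_argument")
})

test_that("bag-of-words aggregation is (min, max, mean) in fixed order", {
  tab <- toy_word_table()  # a=[1,2], b=[3,0]
  emb <- embed_bag_of_words(tab, "a b")
  expect_equal(as.numeric(emb), c(1, 0, 3, 2, 2, 1))
  expect_equal(attr(emb, "parts"), c("min", "max", "mean"))
  expect_equal(attr(emb, "source_level"), "word-aggregated")

  # single word: min = max = mean = the word vector
  single <- embedding_table(matrix(c(4, -1), 1,
                                   dimnames = list("w", NULL)),
                            level = "word")
  expect_equal(as.numeric(embed_bag_of_words(single, "w")),
               c(4, -1, 4, -1, 4, -1))

  # permutation invariance
  expect_equal(as.numeric(embed_bag_of_words(tab, "b a")),
               as.numeric(emb))
})

test_that("bag-of-words segments satisfy min <= mean <= max element-wise", {
  set.seed(42)
  words <- replicate(30, paste(sample(letters, 3), collapse = ""))
  tab <- embedding_table(matrix(rnorm(30 * 5), 30,
                                dimnames = list(words, NULL)),
                         level = "word")
  for (i in 1:20) {
    name <- paste(sample(words, sample(2:5, 1)), collapse = " ")
    v <- as.numeric(embed_bag_of_words(tab, name))
    mins <- v[1:5]; maxs <- v[6:10]; means <- v[11:15]
    expect_true(all(mins <= means + 1e-12))
    expect_true(all(means <= maxs + 1e-12))
  }
})

test_that("out-of-vocabulary policies behave as declared", {
  tab <- toy_word_table()
  expect_error(embed_bag_of_words(tab, "a missing"),
               class = "incembed_missing_entity")
  # skip: missing token dropped
  expect_equal(as.numeric(embed_bag_of_words(tab, "a missing", "skip")),
               c(1, 2, 1, 2, 1, 2))
  # zero: zero vector participates in the aggregation
  expect_equal(as.numeric(embed_bag_of_words(tab, "a missing", "zero")),
               c(0, 0, 1, 2, 0.5, 1))
  # all tokens missing errors under every policy
  for (policy in c("error", "skip", "zero")) {
    expect_error(embed_bag_of_words(tab, "nope nada", policy),
                 class = "incembed_missing_entity")
  }
})

test_that("entity lookup normalizes names and reports missing entities", {
  tab <- toy_entity_table()
  expect_equal(as.numeric(embed_entity(tab, "HIV")),
               unname(tab$vectors["hiv", ]))
  expect_identical(as.numeric(embed_entity(tab, "hiv")),
                   as.numeric(embed_entity(tab, " HIV ")))
  err <- tryCatch(embed_entity(tab, "hiw"), error = identity)
  expect_s3_class(err, "incembed_missing_entity")
  expect_match(conditionMessage(err), "hiv")  # nearest key listed
})

test_that("fusion concatenates in recorded order with additive length", {
  a <- hash_embed("x", 6, 1)
  b <- hash_embed("y", 4, 1)
  c <- hash_embed("z", 8, 1)
  fused <- fuse(list(a, b, c), order_tags = c("A", "B", "C"))
  expect_length(fused, 18)
  expect_equal(attr(fused, "parts"), c("A", "B", "C"))
  expect_equal(as.numeric(fused), c(as.numeric(a), as.numeric(b),
                                    as.numeric(c)))
  # order matters as vectors; both orders are valid records
  expect_false(identical(as.numeric(fuse(list(a, b))),
                         as.numeric(fuse(list(b, a)))))
  # associativity on the flattened result
  expect_equal(as.numeric(fuse(list(fuse(list(a, b)), c))),
               as.numeric(fuse(list(a, fuse(list(b, c))))))
  expect_error(fuse(list(a)), class = "incembed_invalid_argument")
})

test_that("hash embeddings are deterministic, name-keyed and uncorrelated", {
  expect_identical(as.numeric(hash_embed("x", 8, 1)),
                   as.numeric(hash_embed("x", 8, 1)))
  expect_false(identical(as.numeric(hash_embed("x", 8, 1)),
                         as.numeric(hash_embed("y", 8, 1))))
  expect_false(identical(as.numeric(hash_embed("x", 8, 1)),
                         as.numeric(hash_embed("x", 8, 2))))
  # normalization: same key after case/whitespace folding
  expect_identical(as.numeric(hash_embed(" X ", 8, 1)),
                   as.numeric(hash_embed("x", 8, 1)))

  names <- paste("entity", seq_len(100))
  vecs <- t(vapply(names, function(n) as.numeric(hash_embed(n, 64, 3)),
                   numeric(64)))
  sims <- abs(cor(t(vecs)))
  mean_abs_cos <- mean(sims[upper.tri(sims)])
  expect_lt(mean_abs_cos, 0.25)
})

test_that("word2vec text format round-trips within 1e-6", {
  set.seed(1)
  tab <- embedding_table(matrix(rnorm(12), 4, 3,
                                dimnames = list(c("aa", "bb", "cc", "dd"),
                                                NULL)),
                         level = "word", provider_id = "x")
  path <- withr::local_tempfile(fileext = ".txt")
  write_word_vectors(tab, path)
  tab2 <- read_word_vectors(path)
  expect_equal(tab2$dim, 3)
  expect_equal(tab2$vectors[rownames(tab$vectors), ], tab$vectors,
               tolerance = 1e-6)
})

test_that("word2vec loader enforces the format", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("tok1 1 2 3", "tok2 4 5"), path)
  err <- tryCatch(read_word_vectors(path), error = identity)
  expect_s3_class(err, "incembed_format_error")
  expect_match(conditionMessage(err), ":2")  # offending line named

  writeLines(character(), path)
  expect_error(read_word_vectors(path), class = "incembed_format_error")

  # duplicate token: last occurrence wins, with a warning
  writeLines(c("tok 1 2", "tok 3 4"), path)
  expect_warning(tab <- read_word_vectors(path), "duplicate")
  expect_equal(unname(tab$vectors["tok", ]), c(3, 4))

  # optional count/dim header accepted
  writeLines(c("2 3", "a 1 2 3", "b 4 5 6"), path)
  expect_equal(nrow(read_word_vectors(path)$vectors), 2)
})

test_that("providers expose dims and fail with the offending entity named", {
  wtab <- toy_word_table()
  p <- bow_provider(wtab)
  expect_equal(p$dim, 6)
  fp <- fusion_provider(list(p, hash_provider(4, 1)))
  expect_equal(fp$dim, 10)
  expect_equal(fp$embed("a b")[1:6],
               as.numeric(embed_bag_of_words(wtab, "a b")))
  err <- tryCatch(provider_matrix <- incembed:::provider_matrix(p, "zz qq"),
                  error = identity)
  expect_s3_class(err, "incembed_provider_error")
  expect_match(conditionMessage(err), "zz qq")
})
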