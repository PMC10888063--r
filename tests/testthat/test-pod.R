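test_that("filter_corpus keeps documents at or above the character cutoff", {
  rec <- data.frame(id = 1:3, text = strrep("a", c(10, 15, 40)),
                    stringsAsFactors = FALSE)
  kept <- filter_corpus(rec, min_chars = 15)
  expect_equal(nchar(kept$text), c(15, 40))  # "fewer than 15" removed, 15 kept
  expect_equal(nrow(filter_corpus(rec[0, ], 15)), 0)
  # order preserved and relevance predicate applied
  rec2 <- data.frame(text = c(strrep("b", 20), strrep("a", 20)))
  expect_equal(filter_corpus(rec2)$text, rec2$text)
  expect_equal(
    filter_corpus(rec2, relevance_filter = function(t) grepl("a", t))$text,
    strrep("a", 20))
  expect_error(filter_corpus(rec, min_chars = 0), "min_chars")
})

test_that("filter_corpus survivor count matches a brute-force recount", {
  set.seed(5)
  lens <- sample(1:30, 500, replace = TRUE)
  rec <- data.frame(text = vapply(lens, function(l)
    paste(rep("x", l), collapse = ""), character(1)))
  kept <- filter_corpus(rec, min_chars = 15)
  expect_equal(nrow(kept), sum(vapply(rec$text, nchar, 1L) >= 15))
  # idempotence
  expect_identical(filter_corpus(kept, min_chars = 15), kept)
})

test_that("select_vocabulary applies POS, length, stopword, frequency filters", {
  toks <- tokenize_tagged(c("run/v run/v", "tree/n tree/n", "sad/a",
                            "thing/n thing/n thing/n", "z/n z/n"))
  v <- select_vocabulary(toks, min_frequency = 2, stopwords = c("thing"))
  expect_equal(names(v), "tree")   # verb, singleton adj, stopword, 1-char out
  expect_equal(unname(v[["tree"]]), 2L)
  # frequency boundary: 1 excluded, 2 included
  t1 <- tokenize_tagged("cat/n")
  expect_length(select_vocabulary(t1, min_frequency = 2), 0)
  t2 <- tokenize_tagged("cat/n cat/n")
  expect_equal(names(select_vocabulary(t2, min_frequency = 2)), "cat")
  expect_error(select_vocabulary(toks, pos_whitelist = character()),
               "whitelist")
})

test_that("select_vocabulary matches a brute-force count-then-filter pass", {
  set.seed(9)
  pool <- c(sprintf("word%02d/n", 1:20), sprintf("adj%02d/a", 1:10),
            sprintf("verb%02d/v", 1:10), "of/n", "xx/x")
  toks <- tokenize_tagged(paste(sample(pool, 10000, replace = TRUE),
                                collapse = " "))
  got <- select_vocabulary(toks, min_frequency = 5, stopwords = "of")
  # independent pass
  tab <- table(toks$surface)
  ok <- vapply(names(tab), function(w) {
    any(toks$pos[toks$surface == w] %in% c("n", "a")) &&
      nchar(w) >= 2 && w != "of" && tab[[w]] >= 5
  }, logical(1))
  want <- tab[ok]
  expect_setequal(names(got), names(want))
  expect_equal(as.integer(got[names(want)]), as.integer(want))
  # idempotence: re-filtering the surviving tokens changes nothing
  toks2 <- toks[toks$surface %in% names(got), ]
  got2 <- select_vocabulary(toks2, min_frequency = 5, stopwords = "of")
  expect_identical(got, got2)
})

test_that("embedding training is reproducible and has the right shape", {
  toks <- tokenize_tagged(planted_corpus()$text[1:300])
  sents <- split(toks$surface, toks$doc)
  s1 <- train_embeddings(sents, dim = 32, epochs = 3, seed = 99)
  s2 <- train_embeddings(sents, dim = 32, epochs = 3, seed = 99)
  expect_identical(s1$vectors, s2$vectors)
  expect_equal(ncol(s1$vectors), 32)
  expect_equal(rownames(s1$vectors), s1$vocabulary)
  expect_true(all(lengths(apply(s1$vectors, 1, identity, simplify = FALSE)) == 32))
  expect_error(train_embeddings(list()), "empty corpus")
  expect_error(train_embeddings(list("a"), min_count = 2), "corpus too small")
})

test_that("planted words are more target-relevant than the background", {
  space <- planted_embeddings()
  voc <- attr(planted_corpus(), "vocabulary")
  targets <- names(voc$targets)
  planted <- intersect(names(voc$planted), space$vocabulary)
  background <- intersect(names(voc$background), space$vocabulary)
  sim <- function(w) mean(vapply(targets, function(t) {
    a <- space$vectors[w, ]; b <- space$context_vectors[t, ]
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }, numeric(1)))
  ps <- vapply(planted, sim, numeric(1))
  bs <- vapply(background, sim, numeric(1))
  expect_gt(min(ps), quantile(bs, 0.95))
})

test_that("compute_relevance is the clipped mean similarity to the targets", {
  unit <- function(x) x / sqrt(sum(x^2))
  vecs <- rbind(w = c(1, 0), t1 = c(0, 1), t2 = c(0, 1))
  ctx <- rbind(w = c(1, 0),
               t1 = unit(c(0.8, sqrt(1 - 0.64))),
               t2 = unit(c(0.4, sqrt(1 - 0.16))))
  space <- structure(list(vectors = vecs, context_vectors = ctx, dim = 2L,
                          vocabulary = rownames(vecs)),
                     class = "cadi_embeddings")
  # word identical to the sole target
  expect_equal(compute_relevance(space, "t1", "t1"), 1)
  # cosines 0.8 and 0.4 to the two targets average to 0.6
  expect_equal(compute_relevance(space, "w", c("t1", "t2")), 0.6)
  # orthogonal word: clipped at 0
  ctx2 <- rbind(w = c(1, 0), t1 = c(0, 1), t2 = c(0, -1))
  space2 <- structure(list(vectors = vecs, context_vectors = ctx2, dim = 2L,
                           vocabulary = rownames(vecs)),
                      class = "cadi_embeddings")
  expect_equal(compute_relevance(space2, "w", c("t1")), 0)
  expect_error(compute_relevance(space, "nope", "t1"), "nope")
})

test_that("build_pod equals the staged pipeline and enriches planted words", {
  corpus <- planted_corpus()
  voc <- attr(corpus, "vocabulary")
  pod <- build_pod(corpus, seed = 7L)
  expect_s3_class(pod, "cadi_pod")
  expect_true(all(pod$alpha >= 0 & pod$alpha <= 1))
  expect_false(any(duplicated(pod$word)))
  expect_true(all(diff(pod$alpha) <= 0))

  # staged oracle: same word set as running the stages one by one
  filtered <- filter_corpus(corpus, 15)
  toks <- tokenize_tagged(filtered$text)
  vocab <- select_vocabulary(toks, stopwords = default_stopwords())
  space <- train_embeddings(split(toks$surface, toks$doc), seed = 7L)
  want <- intersect(setdiff(names(vocab), c("anxiety", "depression")),
                    space$vocabulary)
  expect_setequal(pod$word, want)

  # enrichment: planted fraction in the top-K at least the candidate fraction
  k <- length(voc$planted)
  frac_top <- mean(pod$word[seq_len(k)] %in% names(voc$planted))
  frac_all <- mean(pod$word %in% names(voc$planted))
  expect_gte(frac_top, frac_all)

  # alpha threshold 1 with no word identical to a target: empty dictionary
  expect_equal(nrow(build_pod(corpus, seed = 7L, alpha_threshold = 1)), 0)
  # size cap respected
  expect_equal(nrow(build_pod(corpus, seed = 7L, max_words = 3)), 3)
})

test_that("tokenizer computes surface character lengths", {
  toks <- tokenize_tagged("anxiety/n z/n gloom01/a")
  expect_equal(toks$char_len, nchar(toks$surface))
  expect_equal(toks$pos, c("n", "n", "a"))
})
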