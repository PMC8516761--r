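test_that("tokenizer lowercases, strips edge punctuation, keeps hyphens and numerals", {
  d <- tokenize_and_stem("")
  expect_equal(d$tokens, character(0))
  expect_equal(d$word_count, 0L)

  d <- tokenize_and_stem("friends, friendly")
  expect_equal(d$stems, c("friend", "friend"))

  d <- tokenize_and_stem("AK-47 ammo!")
  expect_equal(d$tokens, c("ak-47", "ammo"))
  expect_equal(d$stems, c("ak-47", "ammo"))

  d <- tokenize_and_stem("-- ... (fight) 'bullets' 3.5 ---")
  expect_equal(d$tokens, c("fight", "bullets", "3.5"))
  expect_equal(length(d$tokens), length(d$stems))
})

test_that("phrase matching is longest-first, leftmost, per category", {
  lex <- tiny_lexicon()
  doc <- tokenize_and_stem("the last resort", doc_id = "d1")
  spans <- match_terms(doc, lex)
  expect_equal(nrow(spans), 1L)
  expect_equal(spans$term, "last resort")
  expect_equal(spans$start_index, 1L)
  expect_equal(spans$length_tokens, 2L)

  # no lexicon stem present -> empty span table
  doc2 <- tokenize_and_stem("a calm quiet evening")
  expect_equal(nrow(match_terms(doc2, lex)), 0L)

  # a term in two categories yields one span per category
  doc3 <- tokenize_and_stem("fight")
  spans3 <- match_terms(doc3, lex)
  expect_setequal(spans3$category, c("violence", "murder"))
  expect_equal(nrow(spans3), 2L)
})

test_that("proportional and weighted scores follow their definitions", {
  lex <- new_lexicon(
    tibble::tibble(term = c("fight", "bullet"),
                   category = c("violence", "violence"),
                   mean_rating = c(8.2, 6.4),
                   n_ratings = c(9L, 8L)),
    variant = "weighted", schema = "violence")
  filler <- paste(rep("calm", 22), collapse = " ")
  text <- paste("fight fight bullet", filler)  # 25 tokens
  doc <- tokenize_and_stem(text)
  expect_equal(doc$word_count, 25L)

  s <- score_document(doc, lex, mode = "proportional")
  expect_equal(unname(s$scores["violence"]), 3 / 25)
  expect_equal(s$no_match, 22 / 25)
  expect_false(s$short_flag)

  w <- score_document(doc, lex, mode = "weighted")
  expect_equal(unname(w$scores["violence"]), (8.2 + 8.2 + 6.4) / 3)
  expect_true(w$matched["violence"])

  # no matches: proportional all zero, no_match 1; weighted sentinel 0 + flag
  doc0 <- tokenize_and_stem(filler)
  s0 <- score_document(doc0, lex, mode = "proportional")
  expect_equal(unname(s0$scores), 0)
  expect_equal(s0$no_match, 1)
  w0 <- score_document(doc0, lex, mode = "weighted")
  expect_equal(unname(w0$scores), 0)
  expect_false(w0$matched["violence"])

  # zero-length document is an error; weighted needs the weighted variant
  empty <- tokenize_and_stem("")
  expect_error(score_document(empty, lex), "word count is zero")
  expect_error(score_document(doc, tiny_lexicon(), mode = "weighted"),
               "variant 'weighted'")
})

test_that("scoring engine agrees with the brute-force oracle on random docs", {
  fx <- make_lexicon_fixture(n_categories = 5, terms_per_category = 6,
                             multiword_fraction = 0.3, seed = 401)
  lex <- fx$lexicon
  # vocabulary mixing lexicon tokens and fillers so phrases arise by chance
  vocab <- c(unlist(strsplit(lex$term, " ")), fx$filler_vocab[1:30])
  set.seed(402)
  for (i in 1:60) {
    doc <- random_doc(vocab, sample(5:40, 1), sprintf("r%03d", i))
    got <- score_document(doc, lex, mode = "proportional", min_words = 0)
    want <- brute_force_score(doc, lex)
    expect_equal(got$scores, want$scores)
    expect_equal(got$no_match, want$no_match)
    expect_equal(got$tokens_matched, want$tokens_matched)
  }
})

test_that("token coverage conservation holds on every document", {
  fx <- make_lexicon_fixture(n_categories = 4, terms_per_category = 5,
                             multiword_fraction = 0.25, seed = 403)
  vocab <- c(unlist(strsplit(fx$lexicon$term, " ")), fx$filler_vocab[1:20])
  set.seed(404)
  for (i in 1:40) {
    doc <- random_doc(vocab, sample(3:60, 1), sprintf("c%03d", i))
    s <- score_document(doc, fx$lexicon, min_words = 0)
    expect_equal(s$tokens_matched + s$no_match * s$word_count, s$word_count)
    expect_true(all(s$scores >= 0 & s$scores <= 1))
    expect_true(s$no_match >= 0 && s$no_match <= 1)
  }
})

test_that("adding a fresh single-token term never lowers its category score", {
  fx <- make_lexicon_fixture(n_categories = 3, terms_per_category = 4,
                             multiword_fraction = 0, seed = 405)
  lex <- fx$lexicon
  extra <- fx$filler_vocab[1]    # occurs in docs as filler
  vocab <- c(lex$term, fx$filler_vocab[1:10])
  lex2 <- new_lexicon(
    rbind(tibble::as_tibble(lex),
          tibble::tibble(term = extra, category = "planning",
                         mean_rating = 8, n_ratings = 7L)),
    variant = "threshold7", schema = attr(lex, "schema"))
  set.seed(406)
  for (i in 1:25) {
    doc <- random_doc(vocab, sample(5:50, 1), sprintf("m%03d", i))
    s1 <- score_document(doc, lex, min_words = 0)
    s2 <- score_document(doc, lex2, min_words = 0)
    expect_true(s2$scores["planning"] >= s1$scores["planning"])
    # untouched categories unchanged
    expect_equal(s2$scores[c("violence", "weaponry")],
                 s1$scores[c("violence", "weaponry")])
  }
})

test_that("scoring is deterministic across repeated runs", {
  fx <- make_lexicon_fixture(n_categories = 3, terms_per_category = 4,
                             multiword_fraction = 0.5, seed = 407)
  vocab <- c(unlist(strsplit(fx$lexicon$term, " ")), fx$filler_vocab[1:10])
  set.seed(408)
  text <- paste(sample(vocab, 80, replace = TRUE), collapse = " ")
  s1 <- score_document(tokenize_and_stem(text), fx$lexicon)
  s2 <- score_document(tokenize_and_stem(text), fx$lexicon)
  expect_identical(s1, s2)
})

test_that("build_dfm stacks per-document scores with the full column set", {
  lex <- tiny_lexicon()
  texts <- c("fight fight bullet calm", "the last resort of the suicidal man")
  corpus <- tokenize_corpus(texts)
  dfm <- build_dfm(corpus, lex, min_words = 0)
  expect_equal(dim(dfm), c(2L, 4L))
  expect_equal(colnames(dfm), c("violence", "suicide", "murder", "no_match"))
  for (i in 1:2) {
    s <- score_document(corpus[[i]], lex, min_words = 0)
    expect_equal(dfm[i, names(s$scores)], s$scores)
    expect_equal(unname(dfm[i, "no_match"]), s$no_match)
  }
  # empty corpus: zero rows, full column set
  dfm0 <- build_dfm(list(), lex)
  expect_equal(dim(dfm0), c(0L, 4L))

  # term granularity: one column per unique term
  dfmt <- build_dfm(corpus, lex, granularity = "term", min_words = 0)
  expect_equal(ncol(dfmt), length(unique(lex$term)))
  expect_equal(unname(dfmt[1, "fight"]), 2 / 4)

  # round-trip through CSV
  path <- withr::local_tempfile(fileext = ".csv")
  write_dfm(dfm, path)
  expect_equal(read_dfm(path), dfm, ignore_attr = TRUE)
})

test_that("short documents are flagged at the 25-word boundary", {
  corpus <- tokenize_corpus(c(paste(rep("word", 24), collapse = " "),
                              paste(rep("word", 25), collapse = " ")),
                            doc_ids = c("short", "ok"))
  expect_warning(res <- filter_short_documents(corpus), "below the 25-word")
  expect_equal(res$short_ids, "short")
  expect_length(res$corpus, 2L)           # flagged, not removed
  expect_equal(res$dropped_ids, character(0))

  expect_warning(res2 <- filter_short_documents(corpus, drop = TRUE))
  expect_length(res2$corpus, 1L)
  expect_equal(res2$dropped_ids, "short")

  # min_words = 0 is the identity
  expect_silent(res3 <- filter_short_documents(corpus, min_words = 0))
  expect_length(res3$corpus, 2L)
  expect_equal(res3$short_ids, character(0))
})

test_that("chunking cuts sequential windows and flags the partial tail", {
  text <- paste(rep("tok", 250), collapse = " ")
  ch <- chunk_text(text, chunk_size = 100)
  expect_equal(vapply(ch, function(d) d$word_count, integer(1)), c(100L, 100L, 50L))
  expect_equal(vapply(ch, function(d) d$partial, logical(1)), c(FALSE, FALSE, TRUE))

  ch99 <- chunk_text(paste(rep("tok", 99), collapse = " "), chunk_size = 100)
  expect_length(ch99, 1L)
  expect_true(ch99[[1]]$partial)

  expect_length(chunk_text(text, chunk_size = 100, drop_partial = TRUE), 2L)

  # chunk count matches token arithmetic over a multi-text corpus
  set.seed(409)
  lens <- sample(50:450, 22, replace = TRUE)
  texts <- vapply(lens, function(n) paste(rep("tok", n), collapse = " "),
                  character(1))
  total <- sum(vapply(seq_along(texts), function(i) {
    length(chunk_text(texts[i], 100, doc_id = paste0("m", i)))
  }, integer(1)))
  expect_equal(total, sum(ceiling(lens / 100)))
})
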