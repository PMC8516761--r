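test_that("relation expansion adds synonym-set members per category", {
  seeds <- tibble::tibble(category = "weaponry", word = "knife")
  db <- list(knife = c("dagger", "machete", "shiv"))
  out <- expand_with_relations(seeds, db)
  expect_setequal(out$word, c("knife", "dagger", "machete", "shiv"))
  expect_equal(unique(out$category), "weaponry")

  # empty relation sets: identity
  seeds2 <- tibble::tibble(category = c("hate", "hate"), word = c("loathe", "enemy"))
  out2 <- expand_with_relations(seeds2, list())
  expect_equal(out2$word, seeds2$word)

  # overlapping relation sets dedupe to the brute-force union
  db3 <- list(loathe = c("hate", "despise"), enemy = c("foe", "hate"))
  out3 <- expand_with_relations(seeds2, db3)
  expect_setequal(out3$word,
                  union(seeds2$word, union(db3$loathe, db3$enemy)))
})

test_that("embedding expansion recovers planted cluster members by cosine", {
  fx <- make_lexicon_fixture(n_categories = 3, terms_per_category = 10,
                             multiword_fraction = 0, seed = 51)
  emb <- make_embedding_space(fx$lexicon, filler_vocab = fx$filler_vocab,
                              cluster_sd = 0.01, seed = 52)
  cat1 <- attr(fx$lexicon, "schema")[1]
  members <- fx$lexicon$term[fx$lexicon$category == cat1]
  seed_word <- members[1]
  out <- expand_with_embeddings(tibble::tibble(category = cat1, word = seed_word),
                                emb, k = 9)
  expect_setequal(out$word, members)  # the 9 nearest are the other members

  # exhaustive pairwise-cosine oracle for the neighbour set
  unit <- emb / sqrt(rowSums(emb^2))
  sims <- as.numeric(unit %*% unit[seed_word, ])
  names(sims) <- rownames(emb)
  oracle <- names(sort(sims[names(sims) != seed_word], decreasing = TRUE))[1:9]
  expect_setequal(setdiff(out$word, seed_word), oracle)

  # out-of-vocabulary seeds pass through unexpanded
  oov <- expand_with_embeddings(tibble::tibble(category = cat1, word = "zzzz"),
                                emb, k = 9)
  expect_equal(oov$word, "zzzz")
  expect_error(expand_with_embeddings(tibble::tibble(category = cat1,
                                                     word = seed_word),
                                      emb, k = 0))
  # k = 1 on a 2-token vocabulary returns the single other token
  two <- emb[1:2, , drop = FALSE]
  out1 <- expand_with_embeddings(tibble::tibble(category = cat1,
                                                word = rownames(two)[1]),
                                 two, k = 1)
  expect_setequal(out1$word, rownames(two))

  # zero vectors are excluded with a warning
  embz <- rbind(emb, zzzv = rep(0, ncol(emb)))
  expect_warning(expand_with_embeddings(tibble::tibble(category = cat1,
                                                       word = seed_word),
                                        embz, k = 9),
                 "zero vector")
})

test_that("merging keeps cross-category duplicates, drops within-category ones", {
  a <- tibble::tibble(category = c("weaponry", "weaponry"), word = c("knife", "gun"))
  b <- tibble::tibble(category = c("murder", "weaponry"), word = c("knife", "gun"))
  pool <- merge_candidates(a, b)
  expect_equal(sum(pool$word == "knife"), 2L)   # two categories
  expect_equal(sum(pool$word == "gun"), 1L)     # deduped within weaponry
  expect_equal(attr(pool, "total_candidates"), 3L)
  # pool size equals the sum of per-category set unions
  expect_equal(nrow(pool),
               length(union(a$word[a$category == "weaponry"],
                            b$word[b$category == "weaponry"])) +
                 length(b$word[b$category == "murder"]))
})

test_that("rating filter removes failed participants and majority-unknown items", {
  rec <- tibble::tibble(
    participant_id = c("p1", "p1", "p1", "p2", "p2", "p2"),
    word = c("fight", "calm", "check", "fight", "calm", "check"),
    category = c("violence", "violence", "attention",
                 "violence", "violence", "attention"),
    rating = c(8L, 2L, 8L, 7L, 3L, 9L),
    unknown = FALSE,
    is_attention_check = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE),
    attention_expected = c(NA, NA, 9L, NA, NA, 9L))
  res <- filter_ratings(rec)
  # p1 rated the check 8 when 9 was required: every p1 rating is gone
  expect_false("p1" %in% res$records$participant_id)
  expect_equal(nrow(res$records), 2L)
  expect_equal(res$report$n_failed_participants, 1L)
  expect_false(any(res$records$is_attention_check))

  # unknown-majority removal is inclusive at exactly 50%
  rec2 <- tibble::tibble(
    participant_id = paste0("p", 1:7),
    word = "obscure", category = "violence",
    rating = c(NA, NA, NA, NA, 5L, 6L, 7L),
    unknown = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    is_attention_check = FALSE, attention_expected = NA_integer_)
  expect_equal(nrow(filter_ratings(rec2)$records), 0L)  # 4/7 = 57% >= 50%
  rec3 <- rec2[c(1, 2, 5, 6), ]                          # exactly 50%
  expect_equal(nrow(filter_ratings(rec3)$records), 0L)
  rec4 <- rec2[c(1, 5, 6, 7), ]                          # 25% < 50%
  expect_equal(nrow(filter_ratings(rec4)$records), 3L)

  # neither rating nor unknown flag is a validation error
  bad <- rec
  bad$rating[1] <- NA
  expect_error(filter_ratings(bad), "neither a rating nor an unknown flag")

  # idempotence: filtering twice equals filtering once
  once <- filter_ratings(rec)$records
  expect_equal(filter_ratings(once)$records, once)
})

test_that("stem aggregation averages ratings per (stem, category)", {
  rec <- tibble::tibble(
    participant_id = paste0("p", 1:5),
    word = c("friends", "friends", "friends", "friendly", "friends"),
    category = c(rep("relationship", 4), "loneliness"),
    rating = c(8L, 8L, 7L, 9L, 5L),
    unknown = FALSE, is_attention_check = FALSE,
    attention_expected = NA_integer_)
  agg <- aggregate_to_stems(rec)
  rel <- agg[agg$category == "relationship", ]
  expect_equal(rel$term, "friend")          # stemmer oracle: friends/friendly -> friend
  expect_equal(rel$mean_rating, (8 + 8 + 7 + 9) / 4)
  expect_equal(rel$n_ratings, 4L)
  expect_true(all(c("friendly", "friends") %in%
                    strsplit(rel$source_words, ",")[[1]]))
  # same word under a second category aggregates separately
  lon <- agg[agg$category == "loneliness", ]
  expect_equal(lon$mean_rating, 5)
  expect_equal(lon$n_ratings, 1L)
  # means bounded by contributing ratings; n conserved
  expect_true(all(agg$mean_rating >= 5 & agg$mean_rating <= 9))
  expect_equal(sum(agg$n_ratings), nrow(rec))
})

test_that("noiseless end-to-end build recovers the planted lexicon exactly", {
  fx <- make_lexicon_fixture(n_categories = 3, terms_per_category = 4,
                             multiword_fraction = 0, rating_range = c(7, 10),
                             seed = 53)
  planted <- fx$lexicon
  candidates <- tibble::tibble(category = planted$category, word = planted$term)
  true_fit <- stats::setNames(round(planted$mean_rating),
                              paste(planted$term, planted$category, sep = "|"))
  spec <- rating_spec(n_participants = 30, ratings_per_participant = 12,
                      true_fit = true_fit, rating_noise_sd = 0,
                      attention_fail_rate = 0, unknown_rate = 0, seed = 54)
  records <- make_rating_records(spec, candidates)
  built <- build_pipeline(candidates, relation_db = NULL, embeddings = NULL,
                          records = records, variant = "weighted")
  # every planted entry back, with exactly the planted (integer) rating
  got <- tibble::as_tibble(built$lexicon)[c("term", "category", "mean_rating")]
  want <- tibble::tibble(term = planted$term, category = planted$category,
                         mean_rating = round(planted$mean_rating))
  got <- got[order(got$category, got$term), ]
  want <- want[order(want$category, want$term), ]
  expect_equal(got$term, want$term)
  expect_equal(got$category, want$category)
  expect_equal(got$mean_rating, want$mean_rating)
  expect_equal(built$manifest$n_entries, nrow(planted))

  # manifest records stage counts
  expect_equal(built$manifest$n_seed_words, nrow(candidates))
  expect_equal(built$manifest$filter_report$n_failed_participants, 0L)

  # ratings covering no candidate: empty lexicon with a warning
  far <- tibble::tibble(category = "violence", word = "unratedword")
  expect_warning(
    empty <- build_pipeline(far, records = records, variant = "weighted"),
    "empty")
  expect_equal(nrow(empty$lexicon), 0L)
})

test_that("pipeline variant thresholds never add entries as tau rises", {
  fx <- make_lexicon_fixture(n_categories = 2, terms_per_category = 6,
                             rating_range = c(0, 10), variant = "weighted",
                             seed = 55)
  candidates <- tibble::tibble(category = fx$lexicon$category,
                               word = fx$lexicon$term)
  true_fit <- stats::setNames(round(fx$lexicon$mean_rating),
                              paste(fx$lexicon$term, fx$lexicon$category, sep = "|"))
  spec <- rating_spec(n_participants = 40, ratings_per_participant = 9,
                      true_fit = true_fit, rating_noise_sd = 1, seed = 56)
  records <- make_rating_records(spec, candidates)
  key <- function(l) paste(l$term, l$category)
  l7 <- build_pipeline(candidates, records = records, variant = "threshold7")$lexicon
  l5 <- build_pipeline(candidates, records = records, variant = "threshold5")$lexicon
  lw <- build_pipeline(candidates, records = records, variant = "weighted")$lexicon
  expect_true(all(key(l7) %in% key(l5)))
  expect_true(all(key(l5) %in% key(lw)))
  expect_equal(nrow(lw), length(unique(key(lw))))
})

test_that("embedding and rating file formats round-trip", {
  fx <- make_lexicon_fixture(n_categories = 2, terms_per_category = 3, seed = 57)
  emb <- make_embedding_space(fx$lexicon, filler_vocab = fx$filler_vocab[1:5],
                              dim = 6, seed = 58)
  path <- withr::local_tempfile(fileext = ".txt")
  write_embeddings(emb, path)
  emb2 <- read_embeddings(path)
  expect_equal(emb2, emb, tolerance = 1e-6)

  seeds <- tibble::tibble(category = c("violence", "planning"),
                          word = c("fight", "tactic"))
  spath <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(seeds, spath, row.names = FALSE)
  expect_equal(read_seed_lists(spath), seeds)
})
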