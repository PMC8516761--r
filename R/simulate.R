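#' Specification for a synthetic scored corpus
#'
#' Describes a corpus with planted category signal: each token of a
#' document is, independently, an occurrence of a category term with that
#' category's injection rate, and a filler word otherwise. Injection rates
#' are therefore the expected proportional scores, which makes corpora
#' generated this way usable as calibration fixtures for the scoring and
#' comparison machinery.
#'
#' @param n_docs Number of documents.
#' @param doc_length_mean,doc_length_sd Token count distribution (normal,
#'   rounded, floored at 1).
#' @param injection_rates Named numeric vector, category -> rate in [0,1];
#'   rates must sum to at most 1.
#' @param filler_vocab_size Number of distinct filler words to draw from.
#' @param seed Integer seed.
#' @return A `grv_corpus_spec` list.
#' @export
corpus_spec <- function(n_docs, doc_length_mean = 100, doc_length_sd = 0,
                        injection_rates, filler_vocab_size = 200L, seed) {
  stopifnot(n_docs >= 1, doc_length_mean >= 1, doc_length_sd >= 0,
            filler_vocab_size >= 1)
  if (is.null(names(injection_rates)) || any(!nzchar(names(injection_rates)))) {
    stop("injection_rates must be a named vector (category -> rate)")
  }
  if (any(injection_rates < 0) || any(injection_rates > 1)) {
    stop("injection rates must lie in [0,1]")
  }
  if (sum(injection_rates) > 1) {
    stop("injection rates sum to more than 1: infeasible token model")
  }
  if (missing(seed)) stop("a seed is required")
  structure(list(n_docs = as.integer(n_docs),
                 doc_length_mean = doc_length_mean,
                 doc_length_sd = doc_length_sd,
                 injection_rates = injection_rates,
                 filler_vocab_size = as.integer(filler_vocab_size),
                 seed = as.integer(seed)),
            class = "grv_corpus_spec")
}

#' Specification for synthetic crowd ratings
#'
#' Emulates a crowd rating task: each participant rates a fixed number of
#' (word, category) items on the 0-10 scale with truncated integer noise
#' around the item's true fit, four attention checks are interleaved per
#' 100 ratings, a configurable proportion of participants fails a check,
#' and unknown-word flags are drawn per word.
#'
#' @param n_participants Number of raters.
#' @param ratings_per_participant Items rated by each participant
#'   (excluding attention checks).
#' @param true_fit Named numeric vector `"word|category"` -> true rating in
#'   [0,10] (names as `paste(word, category, sep = "|")`), or a single
#'   number used for all items.
#' @param rating_noise_sd SD of the Gaussian noise added before rounding
#'   and clamping to 0-10.
#' @param attention_fail_rate Probability that a participant fails one of
#'   their attention checks.
#' @param unknown_rate Named numeric vector word -> probability a rater
#'   flags the word unknown, or a single number for all words.
#' @param seed Integer seed.
#' @return A `grv_rating_spec` list.
#' @export
rating_spec <- function(n_participants, ratings_per_participant = 100L,
                        true_fit, rating_noise_sd = 1,
                        attention_fail_rate = 0, unknown_rate = 0, seed) {
  stopifnot(n_participants >= 1, ratings_per_participant >= 1,
            rating_noise_sd >= 0,
            attention_fail_rate >= 0, attention_fail_rate <= 1,
            all(unknown_rate >= 0), all(unknown_rate <= 1))
  if (missing(seed)) stop("a seed is required")
  structure(list(n_participants = as.integer(n_participants),
                 ratings_per_participant = as.integer(ratings_per_participant),
                 true_fit = true_fit,
                 rating_noise_sd = rating_noise_sd,
                 attention_fail_rate = attention_fail_rate,
                 unknown_rate = unknown_rate,
                 seed = as.integer(seed)),
            class = "grv_rating_spec")
}

# Pronounceable pseudo-words that the stemmer maps to themselves, so
# matching tests are isolated from stemmer behaviour. Candidates are drawn
# from CV syllables and kept only if they are a stemmer fixed point.
.make_pseudo_words <- function(n, exclude = character(0), min_syl = 2L,
                               max_syl = 3L) {
  consonants <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "t", "v", "z")
  vowels <- c("a", "e", "i", "o", "u")
  out <- character(0)
  guard <- 0L
  while (length(out) < n) {
    guard <- guard + 1L
    if (guard > 200L * n) stop("could not generate enough stem-stable pseudo-words")
    k <- sample(min_syl:max_syl, 1L)
    w <- paste0(paste0(sample(consonants, k, replace = TRUE),
                       sample(vowels, k, replace = TRUE), collapse = ""),
                sample(consonants, 1L))
    if (w %in% out || w %in% exclude) next
    if (stem_words(w) != w) next
    out <- c(out, w)
  }
  out
}

#' Generate a fixture lexicon with a disjoint filler vocabulary
#'
#' Builds a synthetic lexicon of stem-stable pseudo-words (the stemmer is
#' a fixed point on every term, so matching behaviour is isolated from
#' stemming) together with a filler vocabulary disjoint from all lexicon
#' stems. When `n_categories` is at most 22 the shipped schema names are
#' used; beyond that, generated category names.
#'
#' @param n_categories Number of categories.
#' @param terms_per_category Entries per category.
#' @param multiword_fraction Fraction of entries that are two-word phrases.
#' @param rating_range Range the mean ratings are drawn from (uniform);
#'   clipped from below at the variant's threshold.
#' @param variant Variant of the resulting lexicon.
#' @param filler_vocab_size Size of the disjoint filler vocabulary.
#' @param seed Integer seed.
#' @return List with `lexicon` (a `grv_lexicon`) and `filler_vocab`
#'   (character vector).
#' @export
make_lexicon_fixture <- function(n_categories = 22L, terms_per_category = 10L,
                                 multiword_fraction = 0, rating_range = c(7, 10),
                                 variant = "threshold7",
                                 filler_vocab_size = 200L, seed) {
  stopifnot(n_categories >= 1, terms_per_category >= 1,
            multiword_fraction >= 0, multiword_fraction <= 1)
  if (missing(seed)) stop("a seed is required")
  variant <- match.arg(variant, .lexicon_variants)
  lo <- max(rating_range[1], .variant_threshold(variant))
  hi <- max(rating_range[2], lo)
  old <- .push_rng_state()
  set.seed(seed)
  on.exit(old(), add = TRUE)

  cats <- if (n_categories <= 22L) {
    grievance_categories()[seq_len(n_categories)]
  } else {
    c(grievance_categories(), sprintf("category%02d", seq_len(n_categories - 22L)))
  }
  n_entries <- n_categories * terms_per_category
  n_multi <- round(multiword_fraction * n_entries)
  n_words <- n_entries + n_multi  # phrase entries consume two words
  words <- .make_pseudo_words(n_words)
  filler <- .make_pseudo_words(filler_vocab_size, exclude = words)

  multi_flag <- rep(FALSE, n_entries)
  if (n_multi > 0) multi_flag[sample.int(n_entries, n_multi)] <- TRUE
  terms <- character(n_entries)
  wi <- 1L
  for (i in seq_len(n_entries)) {
    if (multi_flag[i]) {
      terms[i] <- paste(words[wi], words[wi + 1L])
      wi <- wi + 2L
    } else {
      terms[i] <- words[wi]
      wi <- wi + 1L
    }
  }
  entries <- tibble::tibble(
    term = terms,
    category = rep(cats, each = terms_per_category),
    mean_rating = round(stats::runif(n_entries, lo, hi), 2),
    n_ratings = sample(7:12, n_entries, replace = TRUE))
  list(lexicon = new_lexicon(entries, variant = variant, schema = cats),
       filler_vocab = filler)
}

#' Generate a corpus with planted category signal
#'
#' Realizes a [corpus_spec()] against a lexicon: each document draws its
#' length, then each token slot is filled with a term of category c with
#' probability `injection_rates[c]` (term uniform within the category;
#' a multiword term contributes its tokens and one occurrence) and with a
#' filler word otherwise. The ground truth records the realized injected
#' occurrence counts, which the proportional scorer should recover
#' exactly on stem-stable fixtures.
#'
#' @param spec A `grv_corpus_spec`.
#' @param lexicon A `grv_lexicon` whose schema covers the spec's
#'   injection-rate names.
#' @param filler_vocab Character vector of filler words disjoint from the
#'   lexicon stems (e.g. from [make_lexicon_fixture()]).
#' @param doc_prefix Prefix for document ids.
#' @return List with `corpus` (list of `grv_document`), `texts` (character
#'   vector), and `truth` (tibble: doc_id, word_count, one occurrence-count
#'   column per injected category).
#' @export
make_scored_corpus <- function(spec, lexicon, filler_vocab,
                               doc_prefix = "doc") {
  stopifnot(inherits(spec, "grv_corpus_spec"), is_lexicon(lexicon),
            length(filler_vocab) >= 1L)
  rates <- spec$injection_rates
  miss <- setdiff(names(rates), unique(lexicon$category))
  if (length(miss)) {
    stop("injection rates name categories without lexicon entries: ",
         paste(miss, collapse = ", "))
  }
  filler <- filler_vocab[seq_len(min(length(filler_vocab), spec$filler_vocab_size))]
  old <- .push_rng_state()
  set.seed(spec$seed)
  on.exit(old(), add = TRUE)

  cat_terms <- lapply(names(rates), function(cat) {
    lexicon$term[lexicon$category == cat]
  })
  names(cat_terms) <- names(rates)
  p <- c(unname(rates), 1 - sum(rates))

  texts <- character(spec$n_docs)
  truth <- matrix(0L, nrow = spec$n_docs, ncol = length(rates),
                  dimnames = list(NULL, names(rates)))
  wc <- integer(spec$n_docs)
  for (i in seq_len(spec$n_docs)) {
    len <- max(1L, round(stats::rnorm(1L, spec$doc_length_mean,
                                      spec$doc_length_sd)))
    slots <- sample.int(length(p), len, replace = TRUE, prob = p)
    tokens <- character(0)
    for (s in slots) {
      if (s <= length(rates)) {
        term <- sample(cat_terms[[s]], 1L)
        tokens <- c(tokens, strsplit(term, " ", fixed = TRUE)[[1]])
        truth[i, s] <- truth[i, s] + 1L
      } else {
        tokens <- c(tokens, sample(filler, 1L))
      }
    }
    texts[i] <- paste(tokens, collapse = " ")
    wc[i] <- length(tokens)
  }
  doc_ids <- sprintf("%s%04d", doc_prefix, seq_len(spec$n_docs))
  corpus <- tokenize_corpus(texts, doc_ids)
  list(corpus = corpus, texts = texts,
       truth = tibble::tibble(doc_id = doc_ids, word_count = wc,
                              tibble::as_tibble(truth)))
}

#' Generate synthetic crowd rating records
#'
#' Realizes a [rating_spec()] for a candidate table: items are dealt to
#' participants round-robin from a shuffled replication of the candidate
#' list (so with enough participants every item is rated repeatedly),
#' ratings are the item's true fit plus truncated integer noise clamped to
#' 0-10, four attention checks are interleaved per 100 ratings, and
#' unknown flags are drawn per word.
#'
#' @param spec A `grv_rating_spec`.
#' @param candidates Data frame with columns `category`, `word`.
#' @return Tibble of rating records (see [filter_ratings()] for columns).
#' @export
make_rating_records <- function(spec, candidates) {
  stopifnot(inherits(spec, "grv_rating_spec"))
  candidates <- .as_seed_table(candidates)
  if (!nrow(candidates)) stop("no candidate words")
  old <- .push_rng_state()
  set.seed(spec$seed)
  on.exit(old(), add = TRUE)

  item_key <- paste(candidates$word, candidates$category, sep = "|")
  fit_for <- function(keys) {
    if (length(spec$true_fit) == 1L && is.null(names(spec$true_fit))) {
      rep(as.numeric(spec$true_fit), length(keys))
    } else {
      v <- spec$true_fit[keys]
      if (anyNA(v)) stop("true_fit lacks entries for: ",
                         paste(utils::head(keys[is.na(v)], 3), collapse = ", "))
      as.numeric(v)
    }
  }
  unk_for <- function(words) {
    if (length(spec$unknown_rate) == 1L && is.null(names(spec$unknown_rate))) {
      rep(as.numeric(spec$unknown_rate), length(words))
    } else {
      v <- spec$unknown_rate[words]
      v[is.na(v)] <- 0
      as.numeric(v)
    }
  }

  total_items <- spec$n_participants * spec$ratings_per_participant
  deck <- integer(0)
  while (length(deck) < total_items) {
    deck <- c(deck, sample.int(nrow(candidates)))
  }
  deck <- deck[seq_len(total_items)]

  n_checks <- max(1L, round(4L * spec$ratings_per_participant / 100))
  rows <- vector("list", spec$n_participants)
  for (pi in seq_len(spec$n_participants)) {
    ix <- deck[((pi - 1L) * spec$ratings_per_participant + 1L):
                 (pi * spec$ratings_per_participant)]
    fit <- fit_for(item_key[ix])
    noise <- if (spec$rating_noise_sd > 0) {
      stats::rnorm(length(ix), 0, spec$rating_noise_sd)
    } else 0
    rating <- pmin(10L, pmax(0L, as.integer(round(fit + noise))))
    unknown <- stats::runif(length(ix)) < unk_for(candidates$word[ix])
    rating[unknown] <- NA_integer_

    expected <- sample(0:10, n_checks, replace = TRUE)
    check_rating <- expected
    if (stats::runif(1) < spec$attention_fail_rate) {
      j <- sample.int(n_checks, 1L)
      check_rating[j] <- (expected[j] + 1L + sample.int(9L, 1L)) %% 11L
    }
    pid <- sprintf("p%04d", pi)
    rows[[pi]] <- rbind(
      tibble::tibble(participant_id = pid,
                     word = candidates$word[ix],
                     category = candidates$category[ix],
                     rating = rating, unknown = unknown,
                     is_attention_check = FALSE,
                     attention_expected = NA_integer_),
      tibble::tibble(participant_id = pid,
                     word = sprintf("attention_check_%d", seq_len(n_checks)),
                     category = "attention",
                     rating = as.integer(check_rating), unknown = FALSE,
                     is_attention_check = TRUE,
                     attention_expected = as.integer(expected)))
  }
  do.call(rbind, rows)
}

#' Generate a planted embedding space for a lexicon
#'
#' One unit-norm center per category; the vectors of a category's
#' single-token terms are the center plus isotropic Gaussian noise
#' (cluster_sd = 0 makes all members pairwise cosine 1); filler tokens get
#' directions approximately uniform on the sphere. Embedding neighbour
#' expansion on such a space recovers a category's members before any
#' filler.
#'
#' @param lexicon A `grv_lexicon` (multiword terms are skipped: embedding
#'   vocabularies are single tokens).
#' @param filler_vocab Character vector of filler tokens to embed.
#' @param dim Embedding dimension (>= 2).
#' @param cluster_sd SD of the within-category noise.
#' @param seed Integer seed.
#' @return Numeric matrix, one row per token, token row names.
#' @export
make_embedding_space <- function(lexicon, filler_vocab = character(0),
                                 dim = 25L, cluster_sd = 0.05, seed) {
  stopifnot(is_lexicon(lexicon), dim >= 2L, cluster_sd >= 0)
  if (missing(seed)) stop("a seed is required")
  old <- .push_rng_state()
  set.seed(seed)
  on.exit(old(), add = TRUE)

  single <- lexicon[!grepl(" ", lexicon$term, fixed = TRUE), , drop = FALSE]
  cats <- unique(single$category)
  centers <- matrix(stats::rnorm(length(cats) * dim), nrow = length(cats))
  centers <- centers / sqrt(rowSums(centers^2))
  rownames(centers) <- cats

  tokens <- character(0)
  vecs <- list()
  for (cat in cats) {
    terms <- unique(single$term[single$category == cat])
    terms <- setdiff(terms, tokens)  # a term keeps its first category's cluster
    if (!length(terms)) next
    noise <- matrix(stats::rnorm(length(terms) * dim, 0, cluster_sd),
                    nrow = length(terms))
    vecs[[length(vecs) + 1L]] <-
      matrix(centers[cat, ], nrow = length(terms), ncol = dim, byrow = TRUE) + noise
    tokens <- c(tokens, terms)
  }
  filler_vocab <- setdiff(filler_vocab, tokens)
  if (length(filler_vocab)) {
    f <- matrix(stats::rnorm(length(filler_vocab) * dim), nrow = length(filler_vocab))
    f <- f / sqrt(rowSums(f^2))
    vecs[[length(vecs) + 1L]] <- f
    tokens <- c(tokens, filler_vocab)
  }
  m <- do.call(rbind, vecs)
  rownames(m) <- tokens
  m
}
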