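#' Expand seed words with a lexical-relation database
#'
#' For each seed, adds all related words (synonym-set members) supplied by
#' the relation backend, keeping the seed's category label. The backend is
#' an interface: either a named list mapping a query word to a character
#' vector of related words, or a function `function(word) character()`.
#' Words absent from the backend contribute only themselves.
#'
#' @param seeds Data frame with columns `category`, `word` (raw seed words).
#' @param relation_db Named list or function giving related words per query.
#' @return Tibble `category`, `word`: seeds plus related words,
#'   deduplicated case-insensitively within category.
#' @export
expand_with_relations <- function(seeds, relation_db) {
  seeds <- .as_seed_table(seeds)
  lookup <- if (is.function(relation_db)) {
    relation_db
  } else {
    function(w) {
      r <- relation_db[[w]]
      if (is.null(r)) character(0) else as.character(r)
    }
  }
  out <- lapply(seq_len(nrow(seeds)), function(i) {
    related <- lookup(seeds$word[i])
    tibble::tibble(category = seeds$category[i],
                   word = c(seeds$word[i], related))
  })
  .dedupe_within_category(do.call(rbind, out))
}

#' Expand seed words with embedding nearest neighbours
#'
#' For each seed present in the embedding vocabulary, appends its `k`
#' nearest vocabulary tokens by cosine similarity (the seed itself
#' excluded). Ties are broken by ascending lexicographic token order so the
#' expansion is deterministic. Seeds absent from the vocabulary pass
#' through unexpanded. Zero vectors have undefined cosine similarity and
#' are excluded from the neighbour search with a warning.
#'
#' @param seeds Data frame with columns `category`, `word`.
#' @param table An embedding table from [read_embeddings()] or
#'   [make_embedding_space()]: numeric matrix, one row per token, with
#'   token row names.
#' @param k Number of nearest neighbours per seed (>= 1).
#' @return Tibble `category`, `word`, deduplicated within category.
#' @export
expand_with_embeddings <- function(seeds, table, k = 10L) {
  seeds <- .as_seed_table(seeds)
  stopifnot(is.matrix(table), nrow(table) >= 1L)
  if (k < 1L) stop("k must be >= 1")
  norms <- sqrt(rowSums(table^2))
  zero <- norms == 0
  if (any(zero)) {
    warning(sprintf("%d zero vector(s) excluded from neighbour search (cosine undefined): %s",
                    sum(zero), paste(utils::head(rownames(table)[zero], 5),
                                     collapse = ", ")))
    table <- table[!zero, , drop = FALSE]
    norms <- norms[!zero]
  }
  unit <- table / norms
  vocab <- rownames(table)
  out <- lapply(seq_len(nrow(seeds)), function(i) {
    w <- tolower(seeds$word[i])
    j <- match(w, vocab)
    if (is.na(j)) {
      return(tibble::tibble(category = seeds$category[i], word = seeds$word[i]))
    }
    sims <- as.numeric(unit %*% unit[j, ])
    sims[j] <- -Inf
    ord <- order(-sims, vocab)
    nn <- vocab[ord[seq_len(min(k, length(vocab) - 1L))]]
    tibble::tibble(category = seeds$category[i], word = c(seeds$word[i], nn))
  })
  .dedupe_within_category(do.call(rbind, out))
}

#' Merge per-category candidate lists into one pool
#'
#' Removes duplicates within each category while keeping cross-category
#' duplicates: the same word may legitimately be a candidate in several
#' categories (e.g. a weapon word in both weaponry and murder).
#'
#' @param ... Data frames with columns `category`, `word`, or a single list
#'   of such data frames.
#' @return Tibble `category`, `word` with a `total_candidates` attribute.
#' @export
merge_candidates <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) && !is.data.frame(parts[[1]])) {
    parts <- parts[[1]]
  }
  pool <- .dedupe_within_category(
    do.call(rbind, lapply(parts, .as_seed_table)))
  attr(pool, "total_candidates") <- nrow(pool)
  pool
}

.as_seed_table <- function(seeds) {
  seeds <- tibble::as_tibble(seeds)
  if (!all(c("category", "word") %in% names(seeds))) {
    stop("seed table needs columns 'category' and 'word'")
  }
  seeds$category <- as.character(seeds$category)
  seeds$word <- as.character(seeds$word)
  if (any(!nzchar(seeds$word))) stop("empty seed word")
  seeds[c("category", "word")]
}

.dedupe_within_category <- function(tab) {
  key <- paste(tab$category, tolower(tab$word), sep = "\r")
  tab[!duplicated(key), , drop = FALSE]
}

#' Filter crowd rating records
#'
#' Applies the three cleaning rules used before aggregation:
#' \enumerate{
#'   \item every rating from any participant who failed at least one
#'     attention check is dropped (failure = any response not exactly equal
#'     to the instructed value);
#'   \item the attention-check records themselves are dropped;
#'   \item any (word, category) item for which 50\% or more of its raters
#'     flagged the word as unknown is removed entirely (inclusive
#'     boundary).
#' }
#'
#' @param records Data frame with columns `participant_id`, `word`,
#'   `category`, `rating` (integer 0-10 or NA), `unknown` (logical),
#'   `is_attention_check` (logical), `attention_expected` (integer or NA).
#' @param unknown_threshold Proportion of unknown flags at or above which
#'   an item is removed.
#' @param unknown_per_word If `TRUE`, compute the unknown proportion per
#'   word across categories instead of per (word, category) item.
#' @return List with `records` (the surviving rating rows) and `report`
#'   (counts and percentages removed at each step).
#' @export
filter_ratings <- function(records, unknown_threshold = 0.5,
                           unknown_per_word = FALSE) {
  records <- .as_rating_table(records)
  n0 <- nrow(records)

  failed <- unique(records$participant_id[
    records$is_attention_check &
      (is.na(records$rating) | records$rating != records$attention_expected)])
  after_attention <- records[!records$participant_id %in% failed, , drop = FALSE]
  n_failed_rows <- n0 - nrow(after_attention)

  work <- after_attention[!after_attention$is_attention_check, , drop = FALSE]
  n_checks <- nrow(after_attention) - nrow(work)

  item_key <- if (unknown_per_word) {
    tolower(work$word)
  } else {
    paste(tolower(work$word), work$category, sep = "\r")
  }
  unk_prop <- tapply(work$unknown, item_key, mean)
  removed_items <- names(unk_prop)[unk_prop >= unknown_threshold]
  keep <- !(item_key %in% removed_items)
  out <- work[keep & !work$unknown, , drop = FALSE]
  n_unknown_dropped <- sum(keep & work$unknown)

  report <- list(
    n_input = n0,
    n_failed_participants = length(failed),
    n_removed_attention_fail = n_failed_rows,
    pct_removed_attention_fail = if (n0) 100 * n_failed_rows / n0 else 0,
    n_attention_check_rows = n_checks,
    n_items_removed_unknown = length(removed_items),
    pct_items_removed_unknown = if (length(unk_prop)) {
      100 * length(removed_items) / length(unk_prop)
    } else 0,
    n_unknown_rows_dropped = n_unknown_dropped,
    n_output = nrow(out)
  )
  list(records = out, report = report)
}

.as_rating_table <- function(records) {
  records <- tibble::as_tibble(records)
  need <- c("participant_id", "word", "category", "rating", "unknown",
            "is_attention_check", "attention_expected")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("rating table lacks column(s): ",
                         paste(miss, collapse = ", "))
  records$unknown <- as.logical(records$unknown)
  records$is_attention_check <- as.logical(records$is_attention_check)
  bad <- is.na(records$rating) & !records$unknown
  if (any(bad)) {
    stop(sprintf("%d record(s) have neither a rating nor an unknown flag (first at row %d)",
                 sum(bad), which(bad)[1]))
  }
  both <- !is.na(records$rating) & records$unknown
  if (any(both)) {
    stop(sprintf("%d record(s) have both a rating and an unknown flag (first at row %d)",
                 sum(both), which(both)[1]))
  }
  chk <- records$is_attention_check & is.na(records$attention_expected)
  if (any(chk)) {
    stop("attention-check record(s) without attention_expected value")
  }
  records
}

#' Aggregate filtered ratings to word stems
#'
#' Stems every rated word (token-wise for multiword phrases) and averages
#' the ratings per (stem, category), so that inflectional variants pool
#' into a single dictionary entry.
#'
#' @param records Filtered rating rows (the `records` element of
#'   [filter_ratings()]).
#' @return Tibble `term` (the stem), `category`, `mean_rating`,
#'   `n_ratings`, `source_words` (comma-joined raw words).
#' @export
aggregate_to_stems <- function(records) {
  records <- tibble::as_tibble(records)
  if (!nrow(records)) {
    return(tibble::tibble(term = character(), category = character(),
                          mean_rating = numeric(), n_ratings = integer(),
                          source_words = character()))
  }
  stem <- stem_terms(records$word)
  key <- paste(stem, records$category, sep = "\r")
  groups <- split(seq_len(nrow(records)), key)
  out <- lapply(groups, function(ix) {
    tibble::tibble(term = stem[ix[1]],
                   category = records$category[ix[1]],
                   mean_rating = mean(records$rating[ix]),
                   n_ratings = length(ix),
                   source_words = paste(sort(unique(tolower(records$word[ix]))),
                                        collapse = ","))
  })
  out <- do.call(rbind, out)
  out[order(out$category, out$term), , drop = FALSE]
}

#' Run the full dictionary construction pipeline
#'
#' Composes the construction stages: relation expansion, embedding
#' expansion, candidate merging, rating filtering (restricted to rated
#' candidates), stem aggregation, and variant selection. A build manifest
#' records counts at every stage together with the parameters.
#'
#' @param seed_lists Data frame with columns `category`, `word`.
#' @param relation_db Relation backend (see [expand_with_relations()]), or
#'   `NULL` to skip relation expansion.
#' @param embeddings Embedding matrix (see [expand_with_embeddings()]), or
#'   `NULL` to skip embedding expansion.
#' @param records Rating records covering (a subset of) the candidates.
#' @param variant Lexicon variant to select.
#' @param k Embedding neighbours per seed.
#' @param schema Optional category schema for the resulting lexicon.
#' @return List with `lexicon` (a `grv_lexicon`) and `manifest` (stage
#'   counts, parameters, filter report).
#' @export
build_pipeline <- function(seed_lists, relation_db = NULL, embeddings = NULL,
                           records, variant, k = 10L, schema = NULL) {
  seeds <- .as_seed_table(seed_lists)
  seeds <- .dedupe_within_category(seeds)
  n_seeds <- nrow(seeds)

  rel <- if (is.null(relation_db)) seeds else expand_with_relations(seeds, relation_db)
  emb <- if (is.null(embeddings)) seeds else expand_with_embeddings(seeds, embeddings, k = k)
  pool <- merge_candidates(rel, emb)

  cand_key <- paste(tolower(pool$word), pool$category, sep = "\r")
  records <- .as_rating_table(records)
  rec_key <- paste(tolower(records$word), records$category, sep = "\r")
  rated <- records[records$is_attention_check | rec_key %in% cand_key, , drop = FALSE]

  filtered <- filter_ratings(rated)
  aggregates <- aggregate_to_stems(filtered$records)
  lexicon <- select_variant(aggregates, variant = variant, schema = schema)
  if (!nrow(lexicon)) {
    warning("ratings cover no candidate words: the built lexicon is empty")
  }
  manifest <- list(
    parameters = list(variant = variant, k = k,
                      relations_used = !is.null(relation_db),
                      embeddings_used = !is.null(embeddings)),
    n_seed_words = n_seeds,
    n_after_relations = nrow(rel),
    n_after_embeddings = nrow(emb),
    n_candidates = nrow(pool),
    n_rating_rows_considered = nrow(rated),
    filter_report = filtered$report,
    n_stem_aggregates = nrow(aggregates),
    n_entries = nrow(lexicon),
    n_unique_terms = length(unique(lexicon$term))
  )
  list(lexicon = lexicon, manifest = manifest)
}

#' Read seed lists from CSV
#'
#' @param path CSV with columns `category,word`.
#' @return Tibble `category`, `word`.
#' @export
read_seed_lists <- function(path) {
  .as_seed_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read rating records from CSV
#'
#' @param path CSV with columns `participant_id,word,category,rating,unknown,is_attention_check,attention_expected`
#'   (empty `rating`/`attention_expected` fields read as NA).
#' @return Validated tibble of rating records.
#' @export
read_rating_records <- function(path) {
  .as_rating_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read a word-embedding table in word-vector text format
#'
#' One token per line followed by its vector components, space-separated
#' (the common plain-text distribution format of pretrained embeddings).
#'
#' @param path Path to the text file.
#' @return Numeric matrix, one row per token, token row names.
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, " ", fixed = TRUE)
  dims <- unique(lengths(parts)) - 1L
  if (length(dims) != 1L || dims < 1L) {
    stop("inconsistent embedding dimensions in ", path)
  }
  tokens <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(tokens)) stop("duplicate token(s) in embedding table")
  m <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(dims)))
  rownames(m) <- tokens
  m
}

#' Write a word-embedding table in word-vector text format
#'
#' @param table Numeric matrix with token row names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(table, path) {
  lines <- vapply(seq_len(nrow(table)), function(i) {
    paste(c(rownames(table)[i],
            format(table[i, ], digits = 8, trim = TRUE, scientific = FALSE)),
          collapse = " ")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
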