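#' Tokenize and stem a text
#'
#' Preprocessing used on both lexicon terms and incoming documents: the text
#' is lowercased, split on whitespace, leading and trailing punctuation is
#' stripped from each token (internal hyphens and apostrophes survive, so
#' entries like `ak-47` are preserved), purely punctuation tokens are
#' dropped, numerals are kept, and every token is stemmed with the Snowball
#' English stemmer ([stem_words()]).
#'
#' @param raw_text A single character string (may be empty).
#' @param doc_id Document identifier carried through scoring.
#' @return A `grv_document`: list with `doc_id`, `raw_text`, `tokens`,
#'   `stems`, `word_count`.
#' @examples
#' d <- tokenize_and_stem("The bullets were fired; fighting ensued.")
#' d$stems
#' @export
tokenize_and_stem <- function(raw_text, doc_id = "doc") {
  stopifnot(length(raw_text) == 1L)
  raw_text <- as.character(raw_text)
  txt <- stringi::stri_trans_tolower(raw_text)
  tokens <- stringi::stri_split_regex(txt, "\\s+", omit_empty = TRUE)[[1]]
  if (length(tokens)) {
    tokens <- stringi::stri_replace_all_regex(
      tokens, "^[^\\p{L}\\p{N}]+|[^\\p{L}\\p{N}]+$", "")
    tokens <- tokens[nzchar(tokens)]
  }
  stems <- stem_words(tokens)
  structure(list(doc_id = doc_id, raw_text = raw_text, tokens = tokens,
                 stems = stems, word_count = length(tokens)),
            class = "grv_document")
}

#' @export
print.grv_document <- function(x, ...) {
  cat(sprintf("<grv_document> '%s': %d tokens\n", x$doc_id, x$word_count))
  invisible(x)
}

#' Tokenize a corpus
#'
#' @param texts Character vector of raw documents.
#' @param doc_ids Document identifiers (default `doc1`, `doc2`, ...).
#' @return List of `grv_document`.
#' @export
tokenize_corpus <- function(texts, doc_ids = NULL) {
  if (is.null(doc_ids)) doc_ids <- paste0("doc", seq_along(texts))
  stopifnot(length(doc_ids) == length(texts))
  out <- Map(tokenize_and_stem, texts, doc_ids)
  names(out) <- doc_ids
  out
}

# Split a validated lexicon into a fast lookup structure: single-token terms
# per category and multiword phrases (as stem vectors) per category.
.index_lexicon <- function(lexicon, categories = NULL) {
  if (is.null(categories)) categories <- lexicon_schema(lexicon)
  term_stems <- strsplit(lexicon$term, " ", fixed = TRUE)
  lens <- lengths(term_stems)
  idx <- lapply(categories, function(cat) {
    sel <- lexicon$category == cat
    list(singles = lexicon$term[sel & lens == 1L],
         phrases = term_stems[sel & lens > 1L],
         phrase_terms = lexicon$term[sel & lens > 1L])
  })
  names(idx) <- categories
  idx
}

# All candidate occurrences of the given terms in a stem sequence.
.candidate_spans <- function(stems, singles, phrases, phrase_terms) {
  n <- length(stems)
  starts <- integer(0); lens <- integer(0); terms <- character(0)
  if (length(singles) && n) {
    hit <- which(stems %in% singles)
    starts <- c(starts, hit)
    lens <- c(lens, rep(1L, length(hit)))
    terms <- c(terms, stems[hit])
  }
  if (length(phrases) && n) {
    for (j in seq_along(phrases)) {
      ph <- phrases[[j]]
      L <- length(ph)
      if (L > n) next
      ok <- stems[seq_len(n - L + 1L)] == ph[1]
      if (L > 1L) {
        for (k in 2:L) ok <- ok & stems[k:(n - L + k)] == ph[k]
      }
      hit <- which(ok)
      starts <- c(starts, hit)
      lens <- c(lens, rep(L, length(hit)))
      terms <- c(terms, rep(phrase_terms[j], length(hit)))
    }
  }
  list(starts = starts, lens = lens, terms = terms)
}

# Greedy longest-match-first, then leftmost, non-overlapping selection.
.resolve_spans <- function(starts, lens, terms, n_tokens) {
  if (!length(starts)) {
    return(list(starts = integer(0), lens = integer(0), terms = character(0)))
  }
  ord <- order(-lens, starts)
  taken <- logical(n_tokens)
  keep <- logical(length(starts))
  for (i in ord) {
    span <- starts[i]:(starts[i] + lens[i] - 1L)
    if (!any(taken[span])) {
      taken[span] <- TRUE
      keep[i] <- TRUE
    }
  }
  list(starts = starts[keep], lens = lens[keep], terms = terms[keep])
}

#' Match lexicon terms in a document
#'
#' Finds all occurrences of lexicon terms in the document's stem sequence.
#' Single-token terms match on stem equality; multiword terms match on
#' consecutive stem equality. Within each category, overlapping candidates
#' are resolved longest-match-first, then leftmost, so a phrase like
#' `last resort` is never additionally counted as its constituent words.
#' A term listed under k categories yields one span per category per
#' occurrence.
#'
#' @param doc A `grv_document`.
#' @param lexicon A `grv_lexicon`.
#' @return Tibble with columns `doc_id`, `term`, `category`,
#'   `start_index` (0-based token offset), `length_tokens`.
#' @export
match_terms <- function(doc, lexicon) {
  stopifnot(inherits(doc, "grv_document"), is_lexicon(lexicon))
  idx <- .index_lexicon(lexicon)
  out <- lapply(names(idx), function(cat) {
    cand <- .candidate_spans(doc$stems, idx[[cat]]$singles,
                             idx[[cat]]$phrases, idx[[cat]]$phrase_terms)
    sel <- .resolve_spans(cand$starts, cand$lens, cand$terms, doc$word_count)
    if (!length(sel$starts)) return(NULL)
    ord <- order(sel$starts)
    tibble::tibble(doc_id = doc$doc_id, term = sel$terms[ord], category = cat,
                   start_index = sel$starts[ord] - 1L,
                   length_tokens = sel$lens[ord])
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(tibble::tibble(doc_id = character(), term = character(),
                          category = character(), start_index = integer(),
                          length_tokens = integer()))
  }
  do.call(rbind, out)
}

#' Score one document against a lexicon
#'
#' Proportional mode follows the word-count convention: the category score
#' is the number of match occurrences in the category divided by the total
#' token count, where a multiword match counts as one occurrence. The
#' `no_match` value is the proportion of tokens not covered by any match of
#' any category. Weighted mode reports the average crowd rating of all match
#' occurrences per category; categories without any match carry the sentinel
#' 0 together with an explicit absent flag, so "no evidence" is
#' distinguishable from "rated 0". Texts under 25 tokens are flagged as too
#' short for trustworthy proportions.
#'
#' @param doc A `grv_document` with `word_count > 0`.
#' @param lexicon A `grv_lexicon`; weighted mode requires the `weighted`
#'   variant, which retains every rated term.
#' @param mode `"proportional"` or `"weighted"`.
#' @param min_words Word count below which the short-document flag is set.
#' @return A `grv_scores` list: `doc_id`, `mode`, `scores` (named numeric
#'   over the schema), `matched` (named logical; weighted sentinel flag),
#'   `no_match`, `tokens_matched`, `word_count`, `short_flag`.
#' @export
score_document <- function(doc, lexicon, mode = c("proportional", "weighted"),
                           min_words = 25L) {
  mode <- match.arg(mode)
  stopifnot(inherits(doc, "grv_document"), is_lexicon(lexicon))
  if (doc$word_count == 0L) {
    stop("cannot score document '", doc$doc_id, "': word count is zero")
  }
  if (mode == "weighted" && lexicon_variant(lexicon) != "weighted") {
    stop("weighted scoring requires a lexicon with variant 'weighted'")
  }
  schema <- lexicon_schema(lexicon)
  spans <- match_terms(doc, lexicon)
  covered <- logical(doc$word_count)
  if (nrow(spans)) {
    for (i in seq_len(nrow(spans))) {
      covered[(spans$start_index[i] + 1L):(spans$start_index[i] + spans$length_tokens[i])] <- TRUE
    }
  }
  scores <- stats::setNames(numeric(length(schema)), schema)
  matched <- stats::setNames(logical(length(schema)), schema)
  if (mode == "proportional") {
    if (nrow(spans)) {
      counts <- table(factor(spans$category, levels = schema))
      scores[] <- as.numeric(counts) / doc$word_count
      matched[] <- as.numeric(counts) > 0
    }
  } else {
    if (nrow(spans)) {
      key_l <- paste(lexicon$term, lexicon$category, sep = "\r")
      key_s <- paste(spans$term, spans$category, sep = "\r")
      w <- lexicon$mean_rating[match(key_s, key_l)]
      means <- tapply(w, factor(spans$category, levels = schema), mean)
      got <- !is.na(means)
      scores[got] <- means[got]
      matched[] <- got
    }
  }
  structure(list(doc_id = doc$doc_id, mode = mode, scores = scores,
                 matched = matched,
                 no_match = (doc$word_count - sum(covered)) / doc$word_count,
                 tokens_matched = sum(covered),
                 word_count = doc$word_count,
                 short_flag = doc$word_count < min_words),
            class = "grv_scores")
}

#' @export
print.grv_scores <- function(x, ...) {
  cat(sprintf("<grv_scores> '%s' (%s): %d/%d tokens matched%s\n", x$doc_id,
              x$mode, x$tokens_matched, x$word_count,
              if (x$short_flag) " [short]" else ""))
  print(round(x$scores, 4))
  invisible(x)
}

#' Build a document-feature matrix
#'
#' Scores every document in a corpus and stacks the results into a matrix
#' with one row per document. At `category` granularity the columns are the
#' lexicon schema plus a final `no_match` column; at `term` granularity
#' there is one column per unique lexicon term, holding the proportional
#' occurrence of that term (matching over the union of all terms with the
#' same longest-first resolution).
#'
#' @param corpus List of `grv_document` (see [tokenize_corpus()]).
#' @param lexicon A `grv_lexicon`.
#' @param mode `"proportional"` or `"weighted"` (category granularity only).
#' @param granularity `"category"` or `"term"`.
#' @param min_words Threshold for the per-document short flag.
#' @return Numeric matrix with `doc_id` row names; attributes `mode`,
#'   `granularity`, `short_flag` (named logical), and for weighted mode
#'   `matched` (document x category logical matrix of the absent-flags).
#' @export
build_dfm <- function(corpus, lexicon, mode = c("proportional", "weighted"),
                      granularity = c("category", "term"), min_words = 25L) {
  mode <- match.arg(mode)
  granularity <- match.arg(granularity)
  stopifnot(is_lexicon(lexicon))
  doc_ids <- vapply(corpus, function(d) d$doc_id, character(1))
  if (granularity == "category") {
    schema <- lexicon_schema(lexicon)
    cols <- c(schema, "no_match")
    mat <- matrix(0, nrow = length(corpus), ncol = length(cols),
                  dimnames = list(doc_ids, cols))
    matched <- matrix(FALSE, nrow = length(corpus), ncol = length(schema),
                      dimnames = list(doc_ids, schema))
    short_flag <- stats::setNames(logical(length(corpus)), doc_ids)
    for (i in seq_along(corpus)) {
      s <- score_document(corpus[[i]], lexicon, mode = mode, min_words = min_words)
      mat[i, schema] <- s$scores
      mat[i, "no_match"] <- s$no_match
      matched[i, ] <- s$matched
      short_flag[i] <- s$short_flag
    }
    structure(mat, mode = mode, granularity = granularity,
              short_flag = short_flag,
              matched = if (mode == "weighted") matched else NULL)
  } else {
    if (mode != "proportional") {
      stop("term granularity is defined for proportional mode only")
    }
    terms <- sort(unique(lexicon$term))
    mat <- matrix(0, nrow = length(corpus), ncol = length(terms),
                  dimnames = list(doc_ids, terms))
    short_flag <- stats::setNames(logical(length(corpus)), doc_ids)
    term_stems <- strsplit(terms, " ", fixed = TRUE)
    lens <- lengths(term_stems)
    singles <- terms[lens == 1L]
    phrases <- term_stems[lens > 1L]
    phrase_terms <- terms[lens > 1L]
    for (i in seq_along(corpus)) {
      doc <- corpus[[i]]
      if (doc$word_count == 0L) {
        stop("cannot score document '", doc$doc_id, "': word count is zero")
      }
      cand <- .candidate_spans(doc$stems, singles, phrases, phrase_terms)
      sel <- .resolve_spans(cand$starts, cand$lens, cand$terms, doc$word_count)
      if (length(sel$terms)) {
        counts <- table(factor(sel$terms, levels = terms))
        mat[i, ] <- as.numeric(counts) / doc$word_count
      }
      short_flag[i] <- doc$word_count < min_words
    }
    structure(mat, mode = mode, granularity = granularity,
              short_flag = short_flag)
  }
}

#' Flag or drop documents below a minimum word count
#'
#' Proportional dictionary scores on very short texts are unstable; the
#' conventional minimum is 25 words. Short documents are always reported
#' with a warning; they are removed only when `drop = TRUE`.
#'
#' @param corpus List of `grv_document`.
#' @param min_words Minimum word count (documents with fewer are short).
#' @param drop Remove the short documents from the returned corpus?
#' @return List with `corpus` (kept documents), `short_ids` (doc ids below
#'   the threshold), `dropped_ids` (ids actually removed).
#' @export
filter_short_documents <- function(corpus, min_words = 25L, drop = FALSE) {
  wc <- unname(vapply(corpus, function(d) d$word_count, integer(1)))
  ids <- unname(vapply(corpus, function(d) d$doc_id, character(1)))
  short <- wc < min_words
  if (any(short)) {
    warning(sprintf("%d document(s) below the %d-word minimum: %s%s",
                    sum(short), min_words,
                    paste(utils::head(ids[short], 5), collapse = ", "),
                    if (drop) " (removed)" else ""))
  }
  list(corpus = if (drop) corpus[!short] else corpus,
       short_ids = ids[short],
       dropped_ids = if (drop) ids[short] else character(0))
}

#' Split a text into sequential fixed-size chunks
#'
#' Draws consecutive non-overlapping windows of `chunk_size` tokens from a
#' text, e.g. to make long manifestos comparable in length to short forum
#' posts. The final partial chunk is kept by default and carries a
#' `partial` flag; set `drop_partial = TRUE` to discard it.
#'
#' @param raw_text A single string.
#' @param chunk_size Tokens per chunk (>= 1).
#' @param doc_id Base identifier; chunks are suffixed `_chunk1`, ...
#' @param drop_partial Drop a trailing chunk shorter than `chunk_size`?
#' @return List of `grv_document`, each with a logical `partial` element.
#' @export
chunk_text <- function(raw_text, chunk_size = 100L, doc_id = "doc",
                       drop_partial = FALSE) {
  stopifnot(chunk_size >= 1L)
  full <- tokenize_and_stem(raw_text, doc_id = doc_id)
  n <- full$word_count
  if (n == 0L) return(list())
  chunk_size <- as.integer(chunk_size)
  starts <- seq.int(1L, n, by = chunk_size)
  chunks <- lapply(seq_along(starts), function(j) {
    from <- starts[j]
    to <- min(from + chunk_size - 1L, n)
    d <- structure(list(doc_id = sprintf("%s_chunk%d", doc_id, j),
                        raw_text = paste(full$tokens[from:to], collapse = " "),
                        tokens = full$tokens[from:to],
                        stems = full$stems[from:to],
                        word_count = to - from + 1L,
                        partial = (to - from + 1L) < chunk_size),
                   class = "grv_document")
    d
  })
  if (drop_partial) {
    chunks <- chunks[!vapply(chunks, function(d) d$partial, logical(1))]
  }
  chunks
}

#' Write a document-feature matrix to CSV
#'
#' @param dfm Matrix from [build_dfm()].
#' @param path Output path; `doc_id` becomes the first column.
#' @return `path`, invisibly.
#' @export
write_dfm <- function(dfm, path) {
  df <- data.frame(doc_id = rownames(dfm), dfm, check.names = FALSE,
                   row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a document-feature matrix from CSV
#'
#' @param path CSV with a `doc_id` column and one numeric column per feature.
#' @return Numeric matrix with `doc_id` row names.
#' @export
read_dfm <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"doc_id" %in% names(df)) stop("DFM CSV lacks a doc_id column")
  m <- as.matrix(df[setdiff(names(df), "doc_id")])
  rownames(m) <- as.character(df$doc_id)
  storage.mode(m) <- "double"
  m
}
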