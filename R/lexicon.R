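#' The shipped 22-category schema
#'
#' The default category schema for grievance-fueled language assessment:
#' 22 psychological and social concepts elicited from threat assessment
#' practitioners (planning, violence, weaponry, help, hate, frustration,
#' suicide, threat, grievance, fixation, desperation, deadline, murder,
#' relationship, loneliness, surveillance, soldier, honor, impostor,
#' jealousy, god, paranoia). The scoring engine itself is
#' dictionary-agnostic: any user-defined schema may be used instead.
#'
#' @return Character vector of 22 lowercase category names.
#' @export
grievance_categories <- function() {
  c("planning", "violence", "weaponry", "help", "hate", "frustration",
    "suicide", "threat", "grievance", "fixation", "desperation", "deadline",
    "murder", "relationship", "loneliness", "surveillance", "soldier",
    "honor", "impostor", "jealousy", "god", "paranoia")
}

.lexicon_variants <- c("threshold7", "threshold5", "weighted")

.variant_threshold <- function(variant) {
  switch(variant, threshold7 = 7, threshold5 = 5, weighted = 0)
}

#' Construct a rating-weighted lexicon
#'
#' A lexicon is a set of (term, category) entries, each carrying the mean
#' crowd rating (0-10 goodness-of-fit) and the number of ratings it is based
#' on. Terms are stored stemmed and lowercase; a term may belong to several
#' categories. Three variants exist: `threshold7` and `threshold5` retain
#' only entries with mean rating at or above 7 resp. 5 (inclusive, used for
#' proportional scoring), while `weighted` retains every rated entry and is
#' the variant used for average-weight scoring.
#'
#' @param entries Data frame with columns `term`, `category`, `mean_rating`,
#'   `n_ratings`.
#' @param variant One of `"threshold7"`, `"threshold5"`, `"weighted"`.
#' @param schema Character vector of admissible categories. Defaults to the
#'   categories present in `entries`.
#' @return An object of class `grv_lexicon`: a tibble of entries with
#'   `variant` and `schema` attributes.
#' @seealso [load_lexicon()], [select_variant()], [validate_lexicon()]
#' @export
new_lexicon <- function(entries, variant, schema = NULL) {
  variant <- match.arg(variant, .lexicon_variants)
  entries <- tibble::as_tibble(entries)
  required <- c("term", "category", "mean_rating", "n_ratings")
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols)) {
    stop("lexicon entries lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  entries <- entries[required]
  entries$term <- as.character(entries$term)
  entries$category <- as.character(entries$category)
  entries$mean_rating <- as.numeric(entries$mean_rating)
  entries$n_ratings <- as.integer(entries$n_ratings)

  if (is.null(schema)) schema <- sort(unique(entries$category))
  if (nrow(entries)) {
    if (any(!nzchar(entries$term))) stop("empty term in lexicon entries")
    bad <- !entries$category %in% schema
    if (any(bad)) {
      stop("categories outside schema: ",
           paste(unique(entries$category[bad]), collapse = ", "))
    }
    out_of_range <- entries$mean_rating < 0 | entries$mean_rating > 10 |
      !is.finite(entries$mean_rating)
    if (any(out_of_range)) {
      stop("mean_rating outside [0,10] for term(s): ",
           paste(utils::head(entries$term[out_of_range], 5), collapse = ", "))
    }
    if (any(entries$n_ratings < 1L)) stop("n_ratings must be positive")
    key <- paste(entries$term, entries$category, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- entries[duplicated(key), , drop = FALSE]
      stop("duplicate (term, category) pair(s): ",
           paste(utils::head(paste0("(", dup$term, ", ", dup$category, ")"), 5),
                 collapse = ", "))
    }
    thr <- .variant_threshold(variant)
    below <- entries$mean_rating < thr
    if (any(below)) {
      stop(sprintf("variant %s requires mean_rating >= %g; violated by %d entr%s (e.g. %s: %g)",
                   variant, thr, sum(below), if (sum(below) == 1) "y" else "ies",
                   entries$term[which(below)[1]],
                   entries$mean_rating[which(below)[1]]))
    }
  }
  structure(entries, class = c("grv_lexicon", class(entries)),
            variant = variant, schema = schema)
}

#' @export
print.grv_lexicon <- function(x, ...) {
  cat(sprintf("<grv_lexicon> variant=%s, %d entries, %d unique terms, %d categories\n",
              attr(x, "variant"), nrow(x), length(unique(x$term)),
              length(attr(x, "schema"))))
  NextMethod()
  invisible(x)
}

#' @rdname new_lexicon
#' @param x Object to test.
#' @export
is_lexicon <- function(x) inherits(x, "grv_lexicon")

lexicon_variant <- function(lexicon) attr(lexicon, "variant")
lexicon_schema <- function(lexicon) attr(lexicon, "schema")

#' Load a lexicon from a tab-separated file
#'
#' Reads the one-row-per-(term, category) TSV format with header
#' `term<TAB>category<TAB>mean_rating<TAB>n_ratings`. Terms are lowercased
#' and re-stemmed defensively on load: scoring requires stem-space equality,
#' so an unstemmed input file would silently fail to match. If re-stemming
#' changes any term a warning names the affected terms.
#'
#' @param path Path to the TSV file.
#' @param variant Lexicon variant (`"threshold7"`, `"threshold5"`,
#'   `"weighted"`); entry ratings must satisfy the variant's threshold.
#' @param schema Optional category schema; defaults to observed categories.
#' @return A [new_lexicon()] object.
#' @export
load_lexicon <- function(path, variant, schema = NULL) {
  variant <- match.arg(variant, .lexicon_variants)
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(lines)) stop("empty lexicon file: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, c("term", "category", "mean_rating", "n_ratings"))) {
    stop("line 1: expected header 'term\\tcategory\\tmean_rating\\tn_ratings', got: ",
         lines[1])
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4L)) {
    bad <- which(nf != 4L)[1]
    stop(sprintf("line %d: expected 4 tab-separated fields, got %d", bad + 1L, nf[bad]))
  }
  m <- matrix(unlist(fields), ncol = 4L, byrow = TRUE)
  rating <- suppressWarnings(as.numeric(m[, 3]))
  nrat <- suppressWarnings(as.integer(m[, 4]))
  if (anyNA(rating)) {
    stop(sprintf("line %d: mean_rating is not a number: '%s'",
                 which(is.na(rating))[1] + 1L, m[which(is.na(rating))[1], 3]))
  }
  if (anyNA(nrat)) {
    stop(sprintf("line %d: n_ratings is not an integer: '%s'",
                 which(is.na(nrat))[1] + 1L, m[which(is.na(nrat))[1], 4]))
  }
  if (any(rating < 0 | rating > 10)) {
    bad <- which(rating < 0 | rating > 10)[1]
    stop(sprintf("line %d: mean_rating %g outside [0,10]", bad + 1L, rating[bad]))
  }
  term_raw <- tolower(m[, 1])
  term <- stem_terms(term_raw)
  changed <- term != term_raw
  if (any(changed)) {
    warning(sprintf("%d term(s) changed by re-stemming on load (e.g. %s); the file appears to contain unstemmed terms",
                    sum(changed),
                    paste(utils::head(sprintf("'%s' -> '%s'",
                                              term_raw[changed], term[changed]), 3),
                          collapse = ", ")))
  }
  entries <- tibble::tibble(term = term, category = tolower(m[, 2]),
                            mean_rating = rating, n_ratings = nrat)
  key <- paste(entries$term, entries$category, sep = "\r")
  if (anyDuplicated(key)) {
    bad <- which(duplicated(key))[1]
    stop(sprintf("line %d: duplicate (term, category) pair ('%s', '%s')",
                 bad + 1L, entries$term[bad], entries$category[bad]))
  }
  new_lexicon(entries, variant = variant, schema = schema)
}

#' Write a lexicon to the tab-separated interchange format
#'
#' @param lexicon A `grv_lexicon`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  stopifnot(is_lexicon(lexicon))
  lines <- c("term\tcategory\tmean_rating\tn_ratings",
             sprintf("%s\t%s\t%s\t%d", lexicon$term, lexicon$category,
                     format(lexicon$mean_rating, digits = 15, trim = TRUE,
                            scientific = FALSE),
                     lexicon$n_ratings))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Select a lexicon variant from stem-level rating aggregates
#'
#' Applies the variant's retention rule to aggregated stem ratings (the
#' output of [aggregate_to_stems()]): `threshold7` keeps entries rated 7 or
#' higher, `threshold5` keeps 5 or higher (both inclusive), and `weighted`
#' keeps every rated entry for average-weight scoring.
#'
#' @param aggregates Data frame with columns `term` (or `stem`), `category`,
#'   `mean_rating`, `n_ratings`.
#' @param variant Variant name.
#' @param schema Optional schema passed through to the lexicon.
#' @return A `grv_lexicon`; empty aggregates give an empty lexicon.
#' @export
select_variant <- function(aggregates, variant, schema = NULL) {
  variant <- match.arg(variant, .lexicon_variants)
  aggregates <- tibble::as_tibble(aggregates)
  if ("stem" %in% names(aggregates) && !"term" %in% names(aggregates)) {
    names(aggregates)[names(aggregates) == "stem"] <- "term"
  }
  if (!nrow(aggregates)) {
    return(new_lexicon(tibble::tibble(term = character(), category = character(),
                                      mean_rating = numeric(), n_ratings = integer()),
                       variant = variant, schema = schema))
  }
  thr <- .variant_threshold(variant)
  keep <- aggregates$mean_rating >= thr
  new_lexicon(aggregates[keep, c("term", "category", "mean_rating", "n_ratings")],
              variant = variant, schema = schema)
}

#' Validate a lexicon and report per-category statistics
#'
#' Report-only validation: nothing is silently repaired. Checks rating
#' range, duplicate (term, category) pairs, and whether stored terms are
#' fixed points of the stemmer, and tabulates entries per category.
#'
#' @param lexicon A `grv_lexicon` (or a data frame with lexicon columns).
#' @return A list of class `grv_lexicon_report` with elements
#'   `n_entries`, `n_terms` (unique terms), `category_counts` (tibble),
#'   `violations` (tibble with columns `type`, `detail`), and `valid`.
#' @export
validate_lexicon <- function(lexicon) {
  entries <- tibble::as_tibble(lexicon)
  schema <- attr(lexicon, "schema")
  if (is.null(schema)) schema <- sort(unique(entries$category))
  violations <- list()
  note <- function(type, detail) {
    violations[[length(violations) + 1L]] <<- tibble::tibble(type = type, detail = detail)
  }
  if (nrow(entries)) {
    oor <- entries$mean_rating < 0 | entries$mean_rating > 10
    for (i in which(oor)) {
      note("rating_range", sprintf("('%s', '%s'): mean_rating %g outside [0,10]",
                                   entries$term[i], entries$category[i],
                                   entries$mean_rating[i]))
    }
    key <- paste(entries$term, entries$category, sep = "\r")
    for (i in which(duplicated(key))) {
      note("duplicate_pair", sprintf("('%s', '%s') appears more than once",
                                     entries$term[i], entries$category[i]))
    }
    restem <- stem_terms(entries$term)
    for (i in which(restem != entries$term)) {
      note("unstemmed_term", sprintf("'%s' stems to '%s'",
                                     entries$term[i], restem[i]))
    }
    outside <- !entries$category %in% schema
    for (i in which(outside)) {
      note("category_outside_schema", sprintf("('%s', '%s')",
                                              entries$term[i], entries$category[i]))
    }
  }
  counts <- table(factor(entries$category, levels = schema))
  category_counts <- tibble::tibble(category = names(counts),
                                    n_entries = as.integer(counts))
  violations <- if (length(violations)) {
    do.call(rbind, violations)
  } else {
    tibble::tibble(type = character(), detail = character())
  }
  structure(list(n_entries = nrow(entries),
                 n_terms = length(unique(entries$term)),
                 category_counts = category_counts,
                 violations = violations,
                 valid = nrow(violations) == 0L),
            class = "grv_lexicon_report")
}

#' @export
print.grv_lexicon_report <- function(x, ...) {
  cat(sprintf("<lexicon report> %d entries, %d unique terms, %d categories; %s\n",
              x$n_entries, x$n_terms, nrow(x$category_counts),
              if (x$valid) "no violations" else
                sprintf("%d violation(s)", nrow(x$violations))))
  if (!x$valid) print(x$violations)
  invisible(x)
}
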