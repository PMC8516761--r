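# Shared fixtures and independent reference implementations ("oracles").
# The oracles deliberately use naive nested-loop logic so they share no code
# path with the package implementation they check.

# A small hand-written lexicon: two categories, one multiword phrase,
# terms already stem-stable.
tiny_lexicon <- function(variant = "threshold7") {
  new_lexicon(
    tibble::tibble(
      term = c("fight", "bullet", "last resort", "suicid", "fight"),
      category = c("violence", "violence", "suicide", "suicide", "murder"),
      mean_rating = c(8.2, 7.4, 9.1, 8.8, 7.9),
      n_ratings = c(9L, 8L, 7L, 10L, 9L)),
    variant = variant,
    schema = c("violence", "suicide", "murder"))
}

# Brute-force proportional scorer: for every category, enumerate all
# (position, term) matches by scanning, then select spans longest-first /
# leftmost with explicit overlap checks against a taken-vector.
brute_force_score <- function(doc, lexicon) {
  stems <- doc$stems
  n <- length(stems)
  schema <- attr(lexicon, "schema")
  occ <- stats::setNames(numeric(length(schema)), schema)
  covered_any <- rep(FALSE, n)
  for (cat in schema) {
    terms <- lexicon$term[lexicon$category == cat]
    cand <- list()
    for (term in terms) {
      parts <- strsplit(term, " ", fixed = TRUE)[[1]]
      L <- length(parts)
      if (L > n) next
      for (start in seq_len(n - L + 1)) {
        hit <- TRUE
        for (j in seq_len(L)) {
          if (stems[start + j - 1] != parts[j]) { hit <- FALSE; break }
        }
        if (hit) cand[[length(cand) + 1]] <- c(start = start, len = L)
      }
    }
    if (!length(cand)) next
    cm <- do.call(rbind, cand)
    cm <- cm[order(-cm[, "len"], cm[, "start"]), , drop = FALSE]
    taken <- rep(FALSE, n)
    for (i in seq_len(nrow(cm))) {
      span <- cm[i, "start"]:(cm[i, "start"] + cm[i, "len"] - 1)
      if (!any(taken[span])) {
        taken[span] <- TRUE
        occ[cat] <- occ[cat] + 1
        covered_any[span] <- TRUE
      }
    }
  }
  list(scores = occ / n, no_match = 1 - sum(covered_any) / n,
       tokens_matched = sum(covered_any))
}

# Independent JZS Bayes factor oracle: composite Simpson's rule on the
# substitution g = u / (1 - u), raw (non-log) integrand.
bf10_oracle <- function(t, n1, n2 = NULL, r = sqrt(2) / 2, n_grid = 20001) {
  if (is.null(n2)) {
    N <- n1; nu <- n1 - 1
  } else {
    N <- n1 * n2 / (n1 + n2); nu <- n1 + n2 - 2
  }
  f <- function(u) {
    g <- u / (1 - u)
    jac <- 1 / (1 - u)^2
    (1 + N * g * r^2)^(-1 / 2) *
      (1 + t^2 / ((1 + N * g * r^2) * nu))^(-(nu + 1) / 2) *
      (2 * pi)^(-1 / 2) * g^(-3 / 2) * exp(-1 / (2 * g)) * jac
  }
  u <- seq(1e-9, 1 - 1e-9, length.out = n_grid)
  h <- u[2] - u[1]
  y <- f(u)
  w <- rep(c(4, 2), length.out = n_grid - 2)
  integral <- h / 3 * (y[1] + sum(w * y[2:(n_grid - 1)]) + y[n_grid])
  integral / (1 + t^2 / nu)^(-(nu + 1) / 2)
}

# Random document over a mixed vocabulary of lexicon tokens and fillers,
# so phrase boundaries and overlaps arise by chance.
random_doc <- function(vocab, len, id) {
  tokens <- sample(vocab, len, replace = TRUE)
  tokenize_and_stem(paste(tokens, collapse = " "), doc_id = id)
}
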