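#' Cronbach's alpha for an item matrix
#'
#' Internal-consistency coefficient over the columns ("items") of a matrix:
#' \deqn{\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_i \mathrm{var}(x_i)}
#' {\mathrm{var}(\sum_i x_i)}\right)}
#' with sample variances (denominator n-1). For category wordlists the
#' items are the per-term proportional occurrences of the category's terms
#' across documents, so alpha measures whether the words of a category
#' co-vary across texts. Alpha is at most 1 and may be negative.
#'
#' @param m Numeric matrix, documents in rows, items in columns
#'   (k >= 2 columns, >= 2 rows).
#' @return The alpha value, or `NA` with a `"reason"` attribute when the
#'   coefficient is undefined (fewer than two items/rows, or zero total
#'   variance).
#' @export
cronbach_alpha <- function(m) {
  m <- as.matrix(m)
  not_computable <- function(reason) {
    structure(NA_real_, reason = reason)
  }
  if (ncol(m) < 2L) return(not_computable("fewer than 2 items"))
  if (nrow(m) < 2L) return(not_computable("fewer than 2 observations"))
  if (!all(is.finite(m))) return(not_computable("non-finite values"))
  k <- ncol(m)
  total_var <- stats::var(rowSums(m))
  if (total_var <= 0) return(not_computable("zero variance of the total score"))
  item_var <- sum(apply(m, 2L, stats::var))
  k / (k - 1) * (1 - item_var / total_var)
}

#' Per-corpus and averaged reliability of one category
#'
#' Builds, for each corpus, the item matrix of per-term proportional
#' occurrences restricted to the category's terms (term-granularity
#' document-feature matrix), computes Cronbach's alpha per corpus, and
#' averages the computable values across corpora. Terms that never occur
#' in a corpus are dropped from that corpus's matrix (they carry no
#' covariance information) and recorded in the result. Documents below the
#' minimum word count are excluded by default.
#'
#' @param corpora List of corpora, each a list of `grv_document`; names are
#'   used as corpus ids.
#' @param lexicon A `grv_lexicon`.
#' @param category Category name present in the lexicon.
#' @param min_words Minimum document word count; shorter documents are
#'   excluded from the item matrix (`0` disables the rule).
#' @return List with `category`, `per_corpus_alpha` (named numeric, NA
#'   where not computable), `mean_alpha`, `dropped_items` (named list of
#'   zero-occurrence terms per corpus).
#' @export
category_reliability <- function(corpora, lexicon, category, min_words = 25L) {
  stopifnot(is_lexicon(lexicon))
  if (!category %in% lexicon$category) {
    stop("category '", category, "' has no entries in the lexicon")
  }
  if (is.null(names(corpora))) {
    names(corpora) <- paste0("corpus", seq_along(corpora))
  }
  terms <- unique(lexicon$term[lexicon$category == category])
  alphas <- stats::setNames(rep(NA_real_, length(corpora)), names(corpora))
  dropped <- stats::setNames(vector("list", length(corpora)), names(corpora))
  for (ci in seq_along(corpora)) {
    corp <- corpora[[ci]]
    if (min_words > 0L) {
      corp <- corp[vapply(corp, function(d) d$word_count >= min_words, logical(1))]
    }
    if (!length(corp)) {
      dropped[[ci]] <- terms
      next
    }
    dfm <- build_dfm(corp, lexicon, mode = "proportional",
                     granularity = "term", min_words = min_words)
    items <- dfm[, colnames(dfm) %in% terms, drop = FALSE]
    zero <- colSums(items) == 0
    dropped[[ci]] <- colnames(items)[zero]
    items <- items[, !zero, drop = FALSE]
    a <- cronbach_alpha(items)
    alphas[ci] <- as.numeric(a)
  }
  computable <- !is.na(alphas)
  list(category = category,
       per_corpus_alpha = alphas,
       mean_alpha = if (any(computable)) mean(alphas[computable]) else NA_real_,
       dropped_items = dropped)
}

#' Reliability report across all categories
#'
#' Convenience wrapper over [category_reliability()] for every category in
#' the lexicon, with the across-category mean and SD of the averaged
#' alphas.
#'
#' @inheritParams category_reliability
#' @return List with `table` (tibble: category, per-corpus alphas,
#'   mean_alpha), `overall_mean`, `overall_sd`.
#' @export
reliability_report <- function(corpora, lexicon, min_words = 25L) {
  cats <- intersect(lexicon_schema(lexicon), unique(lexicon$category))
  rows <- lapply(cats, function(cat) {
    r <- category_reliability(corpora, lexicon, cat, min_words = min_words)
    tibble::tibble(category = cat,
                   mean_alpha = r$mean_alpha,
                   !!!stats::setNames(as.list(r$per_corpus_alpha),
                                      paste0("alpha_", names(r$per_corpus_alpha))))
  })
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$mean_alpha)
  list(table = tab,
       overall_mean = mean(tab$mean_alpha[ok]),
       overall_sd = stats::sd(tab$mean_alpha[ok]))
}

#' Bonferroni-corrected familywise significance threshold
#'
#' The per-test threshold `alpha_fw / n_tests`, reported to two significant
#' digits, as used when screening category-by-reference correlations (22
#' categories at the conventional 0.05 give 0.0023).
#'
#' @param n_tests Number of tests (e.g. number of categories).
#' @param alpha_fw Familywise error rate.
#' @return List with `threshold` (exact) and `threshold_2sig` (2
#'   significant digits).
#' @export
bonferroni_threshold <- function(n_tests, alpha_fw = 0.05) {
  stopifnot(n_tests >= 1)
  thr <- alpha_fw / n_tests
  list(threshold = thr, threshold_2sig = signif(thr, 2))
}

#' Correlate category scores with a reference dictionary
#'
#' Pearson correlations between each lexicon category column and each
#' feature of a pre-computed reference-dictionary document-feature matrix
#' (e.g. general psycholinguistic categories scored by other software),
#' computed per corpus on row-aligned matrices and averaged across corpora.
#' The reported interval is the across-corpus min-max envelope of the
#' per-corpus correlations, alongside a per-corpus Fisher-z 95\% interval.
#' Significance is screened at the Bonferroni-corrected threshold
#' `alpha_fw / n_categories`; a pair is flagged significant when its
#' correlation test clears the threshold in every corpus in which it is
#' computable.
#'
#' @param dfm_self List of category-granularity DFMs (one per corpus), or a
#'   single matrix.
#' @param dfm_ref List of reference DFMs, row-aligned with `dfm_self`
#'   (same documents, same order), or a single matrix.
#' @param alpha_fw Familywise error rate for the Bonferroni screen.
#' @param categories Category columns to correlate; defaults to all
#'   `dfm_self` columns except `no_match`.
#' @return List with `table` (tibble: category, reference_feature,
#'   per-corpus r columns, mean_r, interval_lo/hi, fisher_lo/hi,
#'   significant), `threshold` (2 significant digits), and `top3` (tibble
#'   of the three strongest reference features per category by |mean_r|).
#' @export
correlate_with_reference <- function(dfm_self, dfm_ref, alpha_fw = 0.05,
                                     categories = NULL) {
  if (is.matrix(dfm_self)) dfm_self <- list(dfm_self)
  if (is.matrix(dfm_ref)) dfm_ref <- list(dfm_ref)
  stopifnot(length(dfm_self) == length(dfm_ref))
  if (is.null(names(dfm_self))) {
    names(dfm_self) <- paste0("corpus", seq_along(dfm_self))
  }
  for (i in seq_along(dfm_self)) {
    if (nrow(dfm_self[[i]]) != nrow(dfm_ref[[i]])) {
      stop("corpus ", i, ": self and reference matrices are not row-aligned")
    }
    if (nrow(dfm_self[[i]]) < 3L) {
      stop("corpus ", i, ": need at least 3 documents per corpus")
    }
  }
  if (is.null(categories)) {
    categories <- setdiff(colnames(dfm_self[[1]]), "no_match")
  }
  ref_features <- colnames(dfm_ref[[1]])
  thr <- bonferroni_threshold(length(categories), alpha_fw)
  n_corp <- length(dfm_self)

  rows <- list()
  for (cat in categories) {
    for (rf in ref_features) {
      r <- rep(NA_real_, n_corp)
      p <- rep(NA_real_, n_corp)
      flo <- rep(NA_real_, n_corp)
      fhi <- rep(NA_real_, n_corp)
      for (ci in seq_len(n_corp)) {
        x <- dfm_self[[ci]][, cat]
        y <- dfm_ref[[ci]][, rf]
        if (stats::sd(x) == 0 || stats::sd(y) == 0) next
        ct <- stats::cor.test(x, y, method = "pearson")
        r[ci] <- unname(ct$estimate)
        p[ci] <- ct$p.value
        n <- length(x)
        z <- atanh(max(min(r[ci], 1 - 1e-15), -1 + 1e-15))
        se <- 1 / sqrt(n - 3)
        flo[ci] <- tanh(z - stats::qnorm(0.975) * se)
        fhi[ci] <- tanh(z + stats::qnorm(0.975) * se)
      }
      ok <- !is.na(r)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        category = cat, reference_feature = rf,
        !!!stats::setNames(as.list(r), paste0("r_", names(dfm_self))),
        mean_r = if (any(ok)) mean(r[ok]) else NA_real_,
        interval_lo = if (any(ok)) min(r[ok]) else NA_real_,
        interval_hi = if (any(ok)) max(r[ok]) else NA_real_,
        fisher_lo = if (any(ok)) min(flo[ok]) else NA_real_,
        fisher_hi = if (any(ok)) max(fhi[ok]) else NA_real_,
        n_computable = sum(ok),
        significant = any(ok) && all(p[ok] < thr$threshold)
      )
    }
  }
  tab <- do.call(rbind, rows)
  top3 <- do.call(rbind, lapply(categories, function(cat) {
    sub <- tab[tab$category == cat & !is.na(tab$mean_r), , drop = FALSE]
    sub <- sub[order(-abs(sub$mean_r)), , drop = FALSE]
    utils::head(sub[c("category", "reference_feature", "mean_r",
                      "interval_lo", "interval_hi", "significant")], 3L)
  }))
  list(table = tab, threshold = thr$threshold_2sig, top3 = top3)
}
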