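#' Confusion-matrix metrics
#'
#' Computes the standard binary classification metrics from pooled
#' confusion counts: accuracy, Cohen's kappa (chance agreement from the
#' marginal products), specificity, precision, and recall. A metric whose
#' denominator is zero is reported as `NA` (not computable) without
#' affecting the others.
#'
#' @param tp,fp,tn,fn Confusion counts for the positive class.
#' @param positive_class Label carried through for reporting.
#' @return Tibble with one row: the counts, the five metrics, and
#'   `positive_class`.
#' @export
evaluate_confusion <- function(tp, fp, tn, fn, positive_class = "case") {
  n <- tp + fp + tn + fn
  if (n <= 0) stop("empty confusion matrix")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  accuracy <- (tp + tn) / n
  p_e <- ((tp + fp) * (tp + fn) + (tn + fn) * (tn + fp)) / n^2
  kappa <- if (p_e < 1) (accuracy - p_e) / (1 - p_e) else NA_real_
  tibble::tibble(tp = tp, fp = fp, tn = tn, fn = fn,
                 accuracy = accuracy,
                 kappa = kappa,
                 specificity = ratio(tn, tn + fp),
                 precision = ratio(tp, tp + fp),
                 recall = ratio(tp, tp + fn),
                 positive_class = positive_class)
}

# Multinomial naive Bayes with additive smoothing on features rescaled to
# relative frequencies. Feature values act as (fractional) event counts.
.nb_fit <- function(x, y, smooth = 1) {
  if (any(x < 0)) stop("multinomial naive Bayes requires non-negative features")
  classes <- sort(unique(y))
  rs <- rowSums(x)
  rs[rs == 0] <- 1
  xr <- x / rs
  p <- ncol(x)
  log_lik <- sapply(classes, function(cl) {
    counts <- colSums(xr[y == cl, , drop = FALSE])
    log((counts + smooth) / (sum(counts) + smooth * p))
  })
  log_prior <- log(as.numeric(table(factor(y, levels = classes))) / length(y))
  list(classes = classes, log_lik = log_lik, log_prior = log_prior)
}

.nb_predict <- function(fit, x) {
  rs <- rowSums(x)
  rs[rs == 0] <- 1
  xr <- x / rs
  scores <- xr %*% fit$log_lik
  scores <- sweep(scores, 2L, fit$log_prior, "+")
  fit$classes[max.col(scores, ties.method = "first")]
}

#' Fit a classifier and predict hard labels
#'
#' The three models of the validation protocol:
#' \describe{
#'   \item{`nb`}{multinomial naive Bayes with additive smoothing 1, on
#'     features rescaled to relative frequencies per document (requires
#'     non-negative features);}
#'   \item{`svm`}{linear-kernel support vector machine, cost 1, features
#'     standardized by training-set statistics;}
#'   \item{`rf`}{random forest, 500 trees, `floor(sqrt(p))` candidate
#'     features per split (RNG-dependent; seed the session or use
#'     [cross_validated_task()]).}
#' }
#'
#' @param train_x Numeric training feature matrix.
#' @param train_y Class labels (two classes) for the training rows.
#' @param test_x Feature matrix to predict.
#' @param model `"nb"`, `"svm"`, or `"rf"`.
#' @param ntree,cost Hyperparameters for rf / svm.
#' @return Character vector of predicted labels for `test_x` rows.
#' @export
fit_predict_model <- function(train_x, train_y, test_x,
                              model = c("nb", "svm", "rf"),
                              ntree = 500L, cost = 1) {
  model <- match.arg(model)
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  train_y <- as.character(train_y)
  if (length(unique(train_y)) < 2L) stop("training data must contain both classes")
  if (model == "nb") {
    fit <- .nb_fit(train_x, train_y)
    return(.nb_predict(fit, test_x))
  }
  if (model == "svm") {
    mu <- colMeans(train_x)
    sdev <- apply(train_x, 2L, stats::sd)
    sdev[sdev == 0] <- 1
    tr <- sweep(sweep(train_x, 2L, mu), 2L, sdev, "/")
    te <- sweep(sweep(test_x, 2L, mu), 2L, sdev, "/")
    fit <- e1071::svm(tr, factor(train_y), kernel = "linear", cost = cost,
                      scale = FALSE)
    return(as.character(stats::predict(fit, te)))
  }
  fit <- randomForest::randomForest(train_x, factor(train_y), ntree = ntree,
                                    mtry = max(1L, floor(sqrt(ncol(train_x)))))
  as.character(stats::predict(fit, test_x))
}

# Stratified fold assignment: class proportions preserved per fold.
.stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    ix <- which(y == cl)
    ix <- ix[sample.int(length(ix))]
    fold[ix] <- rep_len(seq_len(n_folds), length(ix))
  }
  fold
}

#' Bootstrap down-sampled cross-validated classification
#'
#' The classification protocol for unbalanced case/control corpora: per
#' bootstrap sample the majority class is down-sampled without replacement
#' to the minority class size; the balanced sample is split into
#' stratified folds (five folds give the 80/20 train/test split);
#' confusion counts are pooled over the folds, converted to metrics with
#' [evaluate_confusion()], and the metrics are averaged across bootstrap
#' samples. When the classes are already balanced and `n_boot = 1` no
#' down-sampling occurs. Deterministic under a fixed seed.
#'
#' @param x Feature matrix (documents x features).
#' @param y Binary class labels per document.
#' @param model `"nb"`, `"svm"`, or `"rf"`.
#' @param n_folds Number of cross-validation folds.
#' @param train_frac Training fraction implied by the fold count; must
#'   equal `1 - 1/n_folds` (present to make the split explicit).
#' @param n_boot Number of bootstrap down-sampling iterations.
#' @param seed Integer seed (required).
#' @param positive_class Class treated as positive; defaults to the
#'   minority class (the case sample).
#' @return A `grv_classification` list: `model`, `metrics` (tibble of
#'   bootstrap-averaged accuracy/kappa/specificity/precision/recall),
#'   `per_boot` (tibble of per-iteration metrics), `n_boot`, `n_folds`,
#'   `positive_class`, `seed`.
#' @export
cross_validated_task <- function(x, y, model = c("nb", "svm", "rf"),
                                 n_folds = 5L, train_frac = 1 - 1 / n_folds,
                                 n_boot = 100L, seed,
                                 positive_class = NULL) {
  model <- match.arg(model)
  x <- as.matrix(x)
  y <- as.character(y)
  stopifnot(nrow(x) == length(y), n_folds >= 2L)
  if (abs(train_frac - (1 - 1 / n_folds)) > 1e-8) {
    stop("train_frac must equal 1 - 1/n_folds (the folds define the split)")
  }
  classes <- sort(unique(y))
  if (length(classes) != 2L) stop("need exactly two classes")
  if (missing(seed)) stop("a seed is required")
  counts <- table(factor(y, levels = classes))
  minority <- classes[which.min(counts)]
  majority <- setdiff(classes, minority)
  if (is.null(positive_class)) positive_class <- minority

  old <- .push_rng_state()
  set.seed(seed)
  on.exit(old(), add = TRUE)

  balanced <- counts[1] == counts[2]
  per_boot <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    if (balanced) {
      xb <- x; yb <- y
    } else {
      maj_ix <- which(y == majority)
      keep <- maj_ix[sample.int(length(maj_ix), min(counts))]
      ix <- sort(c(which(y == minority), keep))
      xb <- x[ix, , drop = FALSE]; yb <- y[ix]
    }
    fold <- .stratified_folds(yb, n_folds)
    tp <- fp <- tn <- fn <- 0L
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      pred <- fit_predict_model(xb[tr, , drop = FALSE], yb[tr],
                                xb[!tr, , drop = FALSE], model = model)
      truth <- yb[!tr]
      tp <- tp + sum(pred == positive_class & truth == positive_class)
      fp <- fp + sum(pred == positive_class & truth != positive_class)
      tn <- tn + sum(pred != positive_class & truth != positive_class)
      fn <- fn + sum(pred != positive_class & truth == positive_class)
    }
    per_boot[[b]] <- evaluate_confusion(tp, fp, tn, fn, positive_class)
  }
  per_boot <- do.call(rbind, per_boot)
  metric_cols <- c("accuracy", "kappa", "specificity", "precision", "recall")
  metrics <- tibble::as_tibble(as.list(colMeans(per_boot[metric_cols],
                                                na.rm = TRUE)))
  structure(list(model = model, metrics = metrics, per_boot = per_boot,
                 n_boot = n_boot, n_folds = n_folds,
                 positive_class = positive_class, seed = seed),
            class = "grv_classification")
}

#' @export
print.grv_classification <- function(x, ...) {
  cat(sprintf("<grv_classification> model=%s, %d bootstrap sample(s) x %d folds, positive class '%s'\n",
              x$model, x$n_boot, x$n_folds, x$positive_class))
  print(round(as.data.frame(x$metrics), 3))
  invisible(x)
}

# Rank-based AUC of a score against binary labels; equals the trapezoidal
# area under the ROC curve over all cutoffs, with ties counted half.
.auc_rank <- function(score, positive) {
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) stop("need both classes for AUC")
  r <- rank(score, ties.method = "average")
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Univariate ROC feature importance
#'
#' Ranks features by how well each one alone separates the two classes:
#' the area under the ROC curve obtained by sweeping a cutoff over the
#' feature values. Direction is ignored (importance
#' `= max(AUC, 1 - AUC)`), so a feature that is systematically lower in
#' the positive class ranks as high as one that is higher. Constant
#' features get AUC 0.5 by convention and are flagged.
#'
#' @param x Feature matrix.
#' @param y Binary labels.
#' @param positive_class Class treated as positive; defaults to the
#'   lexicographically smaller label (direction does not affect ranks).
#' @param top_k Rows to include in the `top` element of the result.
#' @return Tibble `feature`, `auc` (raw, w.r.t. the positive class),
#'   `importance`, `rank`, `constant`; attribute `top` holds the `top_k`
#'   most important features.
#' @export
roc_feature_importance <- function(x, y, positive_class = NULL, top_k = 5L) {
  x <- as.matrix(x)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2L) stop("need exactly two classes")
  if (is.null(positive_class)) positive_class <- classes[1]
  pos <- y == positive_class
  auc <- apply(x, 2L, function(col) {
    if (stats::sd(col) == 0) 0.5 else .auc_rank(col, pos)
  })
  constant <- apply(x, 2L, function(col) stats::sd(col) == 0)
  importance <- pmax(auc, 1 - auc)
  ord <- order(-importance, colnames(x))
  out <- tibble::tibble(feature = colnames(x), auc = unname(auc),
                        importance = unname(importance),
                        constant = unname(constant))
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out <- out[c("feature", "auc", "importance", "rank", "constant")]
  attr(out, "top") <- utils::head(out, top_k)
  out
}
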