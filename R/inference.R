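#' Cohen's d for two independent groups
#'
#' Standardized mean difference `(mean(a) - mean(b)) / s`, positive when
#' the first (case) group scores higher. The default standardizer is the
#' pooled standard deviation
#' `s = sqrt(((n1-1)s1^2 + (n2-1)s2^2) / (n1+n2-2))`; the average-variance
#' form `sqrt((s1^2+s2^2)/2)` is available as an alternative.
#'
#' @param a,b Numeric vectors (case and control group), each of length >= 2.
#' @param method `"pooled"` (default) or `"average"` standardizer.
#' @return The effect size d.
#' @export
cohens_d_independent <- function(a, b, method = c("pooled", "average")) {
  method <- match.arg(method)
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 observations")
  s1 <- stats::var(a); s2 <- stats::var(b)
  s <- if (method == "pooled") {
    sqrt(((n1 - 1) * s1 + (n2 - 1) * s2) / (n1 + n2 - 2))
  } else {
    sqrt((s1 + s2) / 2)
  }
  if (s == 0) stop("zero pooled variance: d is undefined")
  (mean(a) - mean(b)) / s
}

#' Cohen's d for paired observations
#'
#' The within-subject effect size `d_z = mean(diff) / sd(diff)`, positive
#' when the first condition scores higher.
#'
#' @param diff Numeric vector of within-subject differences (length >= 2).
#' @return The effect size d_z.
#' @export
cohens_d_paired <- function(diff) {
  if (length(diff) < 2L) stop("need at least 2 differences")
  s <- stats::sd(diff)
  if (s == 0) stop("zero standard deviation of differences: d_z is undefined")
  mean(diff) / s
}

#' Jeffreys-Zellner-Siow Bayes factor for a t statistic
#'
#' Default-prior Bayes factor BF10 comparing the hypothesis of a group
#' difference against the null, for a one- or two-sample t statistic. The
#' effect size carries a Cauchy prior with scale `prior_scale` and the
#' variance the Jeffreys prior; the marginal likelihood under the
#' alternative is obtained by numerical integration over the Cauchy
#' mixing parameter g:
#' \deqn{BF_{10} = \frac{\int_0^\infty (1+Ngr^2)^{-1/2}
#'   \left(1+\frac{t^2}{(1+Ngr^2)\nu}\right)^{-(\nu+1)/2}
#'   (2\pi)^{-1/2} g^{-3/2} e^{-1/(2g)}\, dg}
#'   {\left(1+\frac{t^2}{\nu}\right)^{-(\nu+1)/2}}}
#' with effective sample size N = n1 (one-sample) or n1 n2/(n1+n2)
#' (two-sample) and degrees of freedom nu = n1-1 resp. n1+n2-2.
#' BF10 is strictly increasing in |t| at fixed n and below 1 at t = 0.
#'
#' @param t Observed t statistic (finite).
#' @param n1 First (or only) group size, >= 2.
#' @param n2 Second group size for the two-sample case, or `NULL`.
#' @param prior_scale Cauchy prior scale r; the conventional default is
#'   `sqrt(2)/2` (0.707).
#' @param log If `TRUE` return log(BF10).
#' @return BF10 (or its log).
#' @export
jzs_bayes_factor <- function(t, n1, n2 = NULL, prior_scale = sqrt(2) / 2,
                             log = FALSE) {
  if (!is.finite(t)) stop("t statistic must be finite")
  if (prior_scale <= 0) stop("prior_scale must be positive")
  if (is.null(n2)) {
    if (n1 < 2L) stop("need n1 >= 2")
    N <- n1
    nu <- n1 - 1
  } else {
    if (n1 < 2L || n2 < 2L) stop("need n1, n2 >= 2")
    N <- n1 * n2 / (n1 + n2)
    nu <- n1 + n2 - 2
  }
  r2 <- prior_scale^2
  log_null <- -(nu + 1) / 2 * log1p(t^2 / nu)
  log_integrand <- function(g) {
    -0.5 * log1p(N * g * r2) -
      (nu + 1) / 2 * log1p(t^2 / ((1 + N * g * r2) * nu)) -
      0.5 * log(2 * pi) - 1.5 * log(g) - 1 / (2 * g)
  }
  # integrate the ratio to the null likelihood, shifted by its maximum for
  # numerical stability at large |t|
  grid <- exp(seq(log(1e-6), log(1e6), length.out = 400))
  lg <- log_integrand(grid) - log_null
  shift <- max(lg)
  val <- stats::integrate(function(g) exp(log_integrand(g) - log_null - shift),
                          lower = 0, upper = Inf,
                          rel.tol = 1e-10, abs.tol = 0,
                          subdivisions = 500L)$value
  lbf <- shift + base::log(val)
  if (log) lbf else exp(lbf)
}

#' Evidence category for a Bayes factor
#'
#' Labels follow the conventional reading used when reporting dictionary
#' group differences: BF10 above 10 is strong evidence for a difference
#' and above 10^3 decisive; boundaries belong to the lower label.
#'
#' @param bf10 Bayes factor(s) in favour of a difference.
#' @return Character vector: `"anecdotal"`, `"moderate"`, `"strong"`, or
#'   `"decisive"`.
#' @export
evidence_label <- function(bf10) {
  stopifnot(all(bf10 > 0))
  out <- rep("anecdotal", length(bf10))
  out[bf10 > 3] <- "moderate"
  out[bf10 > 10] <- "strong"
  out[bf10 > 1e3] <- "decisive"
  out
}

.student_t2 <- function(a, b, welch = FALSE) {
  if (welch) {
    unname(stats::t.test(a, b, var.equal = FALSE)$statistic)
  } else {
    unname(stats::t.test(a, b, var.equal = TRUE)$statistic)
  }
}

#' Bootstrap down-sampled comparison of two groups
#'
#' Compares per-document category scores of a case group against a larger
#' control group by repeatedly down-sampling the control group to the case
#' group's size, computing the two-sample t statistic, Cohen's d, and the
#' JZS Bayes factor on each iteration, and averaging across iterations.
#' The interval reported for d is the 2.5\%/97.5\% percentile interval of
#' the per-iteration values. Down-sampling draws without replacement by
#' default so no control document is duplicated within a t test; drawing
#' with replacement is available via `replace = TRUE`. Results are
#' deterministic under a fixed seed.
#'
#' @param case Numeric vector of case-group scores (the smaller group).
#' @param control Numeric vector of control-group scores,
#'   `length(control) >= length(case)`.
#' @param n_boot Number of bootstrap iterations.
#' @param seed Integer seed (mandatory: all stochastic operations in this
#'   package take explicit seeds).
#' @param replace Sample the control group with replacement?
#' @param welch Use the Welch statistic instead of Student's pooled t?
#' @param prior_scale Cauchy prior scale for the Bayes factor.
#' @return A `grv_comparison` list: `d_mean`, `d_interval`, `t_mean`,
#'   `bf10_mean`, `n_case`, `n_control`, `n_boot`, `design`,
#'   `evidence_label`, `seed`.
#' @export
bootstrap_group_comparison <- function(case, control, n_boot = 100L, seed,
                                       replace = FALSE, welch = FALSE,
                                       prior_scale = sqrt(2) / 2) {
  n1 <- length(case); n2 <- length(control)
  if (n1 < 2L) stop("case group needs at least 2 observations")
  if (n2 < n1) {
    stop("control group is smaller than the case group; swap the roles so the control group is down-sampled")
  }
  if (missing(seed)) stop("a seed is required for the bootstrap")
  old <- .push_rng_state()
  set.seed(seed)
  on.exit(old(), add = TRUE)

  d <- t_stat <- bf <- numeric(n_boot)
  for (i in seq_len(n_boot)) {
    ctl <- if (!replace && n2 == n1) control else {
      control[sample.int(n2, n1, replace = replace)]
    }
    d[i] <- cohens_d_independent(case, ctl)
    t_stat[i] <- .student_t2(case, ctl, welch = welch)
    bf[i] <- jzs_bayes_factor(t_stat[i], n1, n1, prior_scale = prior_scale)
  }
  bf_mean <- mean(bf)
  structure(list(d_mean = mean(d),
                 d_interval = unname(stats::quantile(d, c(0.025, 0.975), type = 7)),
                 t_mean = mean(t_stat),
                 bf10_mean = bf_mean,
                 n_case = n1, n_control = n2, n_boot = n_boot,
                 design = "independent_bootstrap",
                 evidence_label = evidence_label(bf_mean),
                 seed = seed),
            class = "grv_comparison")
}

# Save/restore the RNG state around seeded operations so callers' streams
# are not disturbed.
.push_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", old, envir = globalenv())
  } else {
    function() {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }
  }
}

#' Paired comparison of two within-subject conditions
#'
#' Dependent-samples comparison for designs where each subject produced
#' both texts: paired t test, within-subject effect size d_z, and the
#' one-sample JZS Bayes factor on the differences. No bootstrapping is
#' involved (the samples are equal-sized and aligned), so `n_boot = 1`.
#' The interval for d_z is the normal-approximation 95\% interval
#' `d_z +/- 1.96 * sqrt(1/n + d_z^2/(2n))`.
#'
#' @param cond_a,cond_b Numeric vectors aligned by subject, equal length.
#' @param prior_scale Cauchy prior scale for the Bayes factor.
#' @return A `grv_comparison` list (design `"paired"`).
#' @export
paired_comparison <- function(cond_a, cond_b, prior_scale = sqrt(2) / 2) {
  if (length(cond_a) != length(cond_b)) {
    stop("paired conditions must have equal length (aligned by subject)")
  }
  n <- length(cond_a)
  if (n < 2L) stop("need at least 2 subjects")
  diff <- cond_a - cond_b
  d_z <- cohens_d_paired(diff)
  t_stat <- mean(diff) / (stats::sd(diff) / sqrt(n))
  bf <- jzs_bayes_factor(t_stat, n, prior_scale = prior_scale)
  se <- sqrt(1 / n + d_z^2 / (2 * n))
  structure(list(d_mean = d_z,
                 d_interval = c(d_z - stats::qnorm(0.975) * se,
                                d_z + stats::qnorm(0.975) * se),
                 t_mean = t_stat,
                 bf10_mean = bf,
                 n_case = n, n_control = n, n_boot = 1L,
                 design = "paired",
                 evidence_label = evidence_label(bf),
                 seed = NA_integer_),
            class = "grv_comparison")
}

#' @export
print.grv_comparison <- function(x, ...) {
  cat(sprintf("<grv_comparison> %s: d = %.3f [%.3f; %.3f], t = %.2f, BF10 = %.4g (%s)\n",
              x$design, x$d_mean, x$d_interval[1], x$d_interval[2],
              x$t_mean, x$bf10_mean, x$evidence_label))
  invisible(x)
}

#' Category-wise group comparison table
#'
#' Runs [bootstrap_group_comparison()] (or [paired_comparison()]) for every
#' category column shared by two document-feature matrices and returns the
#' standard comparison table: effect size d with interval, mean t, Bayes
#' factor, and evidence label per category.
#'
#' @param dfm_case,dfm_control Category-granularity DFMs; rows are
#'   documents. For `paired = TRUE` the rows must be subject-aligned.
#' @param paired Use the dependent-samples design?
#' @param n_boot,seed,replace,welch,prior_scale Passed to the comparison.
#' @return Tibble with one row per category.
#' @export
compare_categories <- function(dfm_case, dfm_control, paired = FALSE,
                               n_boot = 100L, seed = NULL, replace = FALSE,
                               welch = FALSE, prior_scale = sqrt(2) / 2) {
  cats <- setdiff(intersect(colnames(dfm_case), colnames(dfm_control)),
                  "no_match")
  if (!length(cats)) stop("no shared category columns")
  rows <- lapply(cats, function(cat) {
    res <- if (paired) {
      paired_comparison(dfm_case[, cat], dfm_control[, cat],
                        prior_scale = prior_scale)
    } else {
      if (is.null(seed)) stop("a seed is required for the bootstrap design")
      bootstrap_group_comparison(dfm_case[, cat], dfm_control[, cat],
                                 n_boot = n_boot, seed = seed,
                                 replace = replace, welch = welch,
                                 prior_scale = prior_scale)
    }
    tibble::tibble(category = cat, d = res$d_mean,
                   d_lo = res$d_interval[1], d_hi = res$d_interval[2],
                   t = res$t_mean, bf10 = res$bf10_mean,
                   evidence = res$evidence_label)
  })
  do.call(rbind, rows)
}
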