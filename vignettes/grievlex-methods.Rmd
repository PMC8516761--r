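---
title: "Scoring, building, and validating rating-weighted lexicons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, building, and validating rating-weighted lexicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grievlex)
```

## The measurement model

A rating-weighted psycholinguistic lexicon is a set of (term, category)
entries. Categories name psychological or social constructs — the shipped
schema has 22 of them, elicited from threat assessment practitioners
(planning, violence, weaponry, ..., paranoia; see
`grievance_categories()`) — and each entry carries the mean of crowd
ratings, on a 0–10 scale, of how well the term fits its category, plus the
number of ratings behind that mean. A term may belong to several
categories: "knife" is evidence of both weaponry and murder talk.

All matching happens in *stem space*. Both lexicon terms and document
tokens are lowercased and reduced with the Snowball English stemmer
(`stem_words()`), the revision of Porter's suffix-stripping algorithm
used throughout word-count text analysis. The stemmer is implemented in
this package directly from the published algorithm definition (regions R1
and R2, consonantal-`y` marking, the exceptional forms, suffix steps 0–5)
so the whole toolchain is self-contained. Two consequences users should
know about:

* algorithmic stemming is not a lemmatizer: "friendship" keeps its
  `-ship` suffix and does **not** merge with "friend"/"friendly", which
  the stemmer does merge;
* the stemmer is not idempotent on every string (the stem of "overdose"
  is "overdos", which re-stems to "overdo"), which is why
  `load_lexicon()` defensively re-stems stored terms and warns if
  anything changes rather than silently trusting the file.

### Document scores

`tokenize_and_stem()` lowercases, splits on whitespace, strips
punctuation only at token edges (so "ak-47" and "o'clock" survive
intact), drops purely punctuation tokens, keeps numerals, and stems.
Given a document of $n$ tokens and a lexicon, matching
(`match_terms()`) proceeds per category: single-token terms match on stem
equality and multiword terms on consecutive stem equality, with
overlapping candidates resolved longest-match-first, then leftmost. This
makes "last resort" one suicide occurrence, never additionally a match of
"last".

Two scoring modes (`score_document()`):

* **proportional** — `score(c) = occurrences(c) / n`, where a multiword
  match counts as one occurrence but covers all its tokens; `no_match` is
  the fraction of tokens covered by no span of any category. Keeping the
  raw token count in the denominator keeps every score in $[0, 1]$ and
  makes conservation exact: covered tokens plus `no_match * n` equal `n`.
* **weighted** — `score(c)` is the mean crowd rating over the match
  occurrences of category `c` (the `weighted` lexicon variant retains
  every rated entry for this purpose). A category without matches reports
  the sentinel 0 together with an explicit absent flag, because
  downstream statistics must distinguish "no evidence" from "rated 0".

Proportions on very short texts are noisy; following word-count practice
the package flags documents under 25 tokens (`filter_short_documents()`,
removal on request only). `chunk_text()` cuts long documents into
sequential 100-token windows so manifesto-length texts become comparable
to forum posts; the trailing partial chunk is kept and flagged by
default, with `drop_partial = TRUE` for analyses that need near-uniform
lengths.

### Lexicon variants

From stem-level aggregates three variants are drawn (`select_variant()`):
`threshold7` keeps entries with mean rating at or above 7, `threshold5`
at or above 5 — both inclusive, matching the "7 or higher" reading — and
`weighted` keeps everything. The variants nest, and the loader reports
both entry counts and unique-term counts since multi-category membership
makes the former exceed the latter.

## Construction pipeline

`build_pipeline()` composes:

1. **Relation expansion** (`expand_with_relations()`): each seed word is
   joined by its synonym-set members from a lexical-relation backend. The
   backend is a plain interface (named list or function), so tests inject
   fixture tables and a WordNet-style database can be plugged in where
   available.
2. **Embedding expansion** (`expand_with_embeddings()`): each seed
   present in a pretrained embedding vocabulary contributes its `k = 10`
   nearest tokens by cosine similarity. Ties are broken lexicographically
   for determinism; zero vectors are excluded (cosine undefined) with a
   warning. Neighbours are drawn from the full vocabulary, as with a
   general pretrained space, not just from already-seen words.
3. **Merging** (`merge_candidates()`): duplicates are removed within a
   category; cross-category duplicates are deliberately retained.
4. **Rating filters** (`filter_ratings()`): participants failing any
   attention check lose all their ratings (failure means any response not
   exactly the instructed value — the instruction is exact); check items
   are dropped; and any item whose raters flagged it unknown at 50% or
   more (inclusive) is removed. The unknown rule is applied per
   (word, category) item by default, with a per-word alternative behind a
   flag, since the aggregation level is genuinely ambiguous.
5. **Stem aggregation** (`aggregate_to_stems()`): ratings are averaged
   per (stem, category), pooling inflectional variants; source words are
   recorded.
6. **Variant selection**, plus a JSON-able manifest of counts at every
   stage.

## Psychometric evaluation

`cronbach_alpha()` computes
$\alpha = \frac{k}{k-1}\bigl(1 - \sum_i s_i^2 / s_T^2\bigr)$ with sample
variances. For a category the "items" are the per-term proportional
occurrences across documents (term-granularity DFM restricted to the
category), computed per corpus and averaged across corpora
(`category_reliability()`); terms never occurring in a corpus are dropped
from that corpus's matrix with a log entry, carrying no covariance
information. Undefined cases (one item, zero total variance) return an
explicit not-computable marker rather than a number.

`correlate_with_reference()` takes pre-computed document-feature matrices
from a reference dictionary — proprietary wordlists are never read, only
their scores — and reports per-corpus Pearson correlations, their mean,
and two labelled intervals: the across-corpus min–max envelope and a
per-corpus Fisher-z 95% interval. How published tables of this kind
formed their intervals is usually unstated, so both defensible readings
are reported rather than asserting either. Significance is screened at
the Bonferroni threshold `alpha_fw / n_categories` (0.05/22 prints as
0.0023), using the category count of the lexicon in use, not a
hard-coded 22; a pair is flagged only when it clears the threshold in
every corpus where it is computable, the conservative choice.

## Group comparison

`bootstrap_group_comparison()` compares per-document category scores of a
small case corpus against a much larger control corpus: the control group
is repeatedly down-sampled to the case size, and the two-sample t
statistic, Cohen's d, and the JZS Bayes factor are averaged over 100
iterations. Down-sampling draws **without** replacement by default — a t
test on duplicated documents is hard to defend — with a with-replacement
mode behind a flag, since "down-sampled through bootstrapping" admits
both readings. The interval on d is the 2.5/97.5 percentile interval of
the per-iteration values; at realistic sizes (thousands of chunks) it is
extremely narrow, which matches how such tables look in print. Student's
pooled-variance t is the default ("independent samples t test" in its
classic sense); Welch is a flag. Cohen's d uses the pooled-SD form, with
the average-SD variant labelled and available, because the exact variant
behind any given paper is often unstated.

`paired_comparison()` handles within-subject designs (each participant
wrote both texts): paired t, the difference-standardized effect size
$d_z$, and a one-sample Bayes factor on the differences; no
bootstrapping, as the samples are equal-sized and aligned.

The Bayes factor (`jzs_bayes_factor()`) integrates the
Jeffreys–Zellner–Siow marginal likelihood numerically, with the
conventional Cauchy prior scale $\sqrt{2}/2$. The integrand is evaluated
in log space as a ratio to the null likelihood and shifted by its maximum
before quadrature, so the engine stays accurate for |t| well beyond
anything a text comparison produces; the test suite holds it within 1% of
an independent Simpson-rule oracle on a (t, n) grid. Evidence labels
follow the conventional reading — above 10 strong, above $10^3$ decisive,
boundaries belonging to the lower label.

## Classification harness

`cross_validated_task()` mirrors the validation protocol for unbalanced
corpora: per bootstrap sample the majority class is down-sampled without
replacement to the minority size, stratified five-fold cross-validation
yields an 80/20 split, confusion counts are pooled over folds (pooled
counts are stabler than per-fold metrics at small n), and metrics are
averaged over 100 bootstrap samples. Three models: a hand-written
multinomial naive Bayes (additive smoothing 1 on relative-frequency
features), a linear SVM (cost 1, standardized by training-fold
statistics), and a random forest (500 trees, $\lfloor\sqrt{p}\rfloor$
split candidates). Hyperparameters are common toolkit defaults; the
positive class defaults to the minority (case) sample.
`evaluate_confusion()` reports accuracy, Cohen's kappa, specificity,
precision, and recall, with zero-denominator metrics individually marked
not computable. `roc_feature_importance()` ranks features by univariate
AUC folded for direction (`max(AUC, 1 - AUC)`), computed as the
rank/Mann–Whitney statistic, which equals the trapezoidal area over all
cutoffs; constant features get 0.5 by convention and a flag.

## Synthetic fixtures: what they do and do not show

The generators in `make_lexicon_fixture()`, `make_scored_corpus()`,
`make_rating_records()`, and `make_embedding_space()` exist so that the
entire toolchain is testable without any external download. Lexicon
fixtures use pronounceable pseudo-words chosen to be stemmer fixed
points, isolating matching logic from stemming (inflected real-word
fixtures exercise the stemmer separately). Corpora plant a per-token
injection rate per category, so the expected proportional score *is* the
rate and calibration is checkable against binomial error; rating fixtures
plant true fits with truncated integer noise, four attention checks per
100 ratings, and configurable failure and unknown rates. All generators
are pure functions of (spec, seed).

What passing these tests shows: the mechanics — matching, counting,
filtering, aggregation, statistics — are correct, calibrated, and
deterministic. What they do not show: anything about real grievance-fueled
text. The fixtures have no topic structure, no vocabulary overlap between
inflection and meaning, no dependence between category usage and
document length. Classifier accuracies on planted fixtures are
separability checks of the harness, not performance claims.

## Numerical and design choices

* Thresholds 7 and 5 and the 50% unknown boundary are inclusive, per
  their "or higher" / "or more" wording.
* Multiword matches count once in the numerator while the denominator
  stays the raw token count; tokens under a phrase count as matched for
  `no_match`. The alternative (counting a phrase's tokens in the
  numerator) can push scores above 1 and was rejected.
* Greedy longest-match-first selection is deterministic and prevents
  double counting, at the price that adding a phrase overlapping existing
  single-word entries can *reorganize* matches; monotonicity of a
  category's score under added entries is guaranteed for single-token
  additions that do not nest with existing phrases.
* Whether published chunking dropped trailing partial chunks is not
  recoverable from summary statistics; both behaviours are supported and
  the default keeps and flags the partial chunk.
* Embedding ties broken lexicographically; all stochastic operations take
  mandatory integer seeds, restore the caller's RNG state, and record the
  seed in their outputs.
* The multinomial NB normalizes each document to relative frequencies;
  as a consequence duplicating a feature column can shift a small number
  of predictions (the per-document normalizer changes). Its univariate
  AUCs are exactly invariant under duplication; test expectations state
  the invariance at the level where it actually holds.
* Alpha item matrices use raw proportions (not presence/absence),
  matching the "proportional occurrence" definition.

Problem sizes used by the test suite and the acceptance script — 1,000
random documents for the scorer-versus-oracle check, 100,000 rows for the
compound-symmetry alpha check, 5,000 per group for d recovery, 200
documents per class for the classification fixtures — were chosen as the
smallest sizes at which the Monte-Carlo error is comfortably below each
check's tolerance.

## Known limitations

* No lemmatization, negation scoping, or word-sense disambiguation:
  "I would never fight" scores as violence talk. This is inherent to
  word-count dictionaries, not an implementation artifact.
* Internal consistency of wordlist categories is structurally low
  (concepts are rarely repeated within a text); alpha values should be
  read comparatively, not against questionnaire conventions.
* The construction pipeline reproduces published dictionary sizes only
  when run on the corresponding deposited seed words, rating tables, and
  embedding files; those artifacts are consumed, never shipped.
* Scores on texts under 25 words are flagged for a reason; proportions on
  ten-token messages are mostly noise.
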