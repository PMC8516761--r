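# grievlex

Construction, scoring, and validation of multi-category, rating-weighted
psycholinguistic lexicons, for researchers and threat assessment
practitioners who measure grievance-fueled language — threats, extremist
manifestos, targeted abuse — with transparent word-count methods rather
than black-box classifiers.

A lexicon here is a set of (term, category) entries over a category schema
(the shipped default has 22 threat-assessment constructs: planning,
violence, weaponry, help, hate, frustration, suicide, threat, grievance,
fixation, desperation, deadline, murder, relationship, loneliness,
surveillance, soldier, honor, impostor, jealousy, god, paranoia). Every
entry carries the mean crowd rating of how well the term fits the category
on a 0–10 scale. Matching runs in stem space (Snowball English stemmer,
implemented in the package) and supports multiword phrases such as
"last resort".

For a document of $n$ tokens, the **proportional** score of category $c$ is

$$\mathrm{score}(c) = \frac{\#\{\text{match occurrences in } c\}}{n},$$

with a phrase counting as one occurrence, plus a `no_match` column — the
fraction of tokens covered by no category. The **weighted** score is the
mean 0–10 rating of the matched entries. Lexicon variants `threshold7` and
`threshold5` retain entries rated at or above 7 resp. 5 (inclusive);
`weighted` keeps every rated entry.

Around this core the package implements the full validation toolchain:

* **Construction** — seed words expanded through a lexical-relation
  backend and embedding cosine nearest neighbours, crowd ratings cleaned
  (attention-check failures, majority-unknown items) and averaged per word
  stem (`build_pipeline()`).
* **Psychometrics** — Cronbach's alpha of each category over per-term
  proportional occurrences, averaged across corpora; correlations with a
  reference dictionary's score matrix under a Bonferroni screen
  (`category_reliability()`, `correlate_with_reference()`).
* **Group comparison** — bootstrap down-sampled independent comparisons
  and paired comparisons: Student t, Cohen's d with interval, and the JZS
  default Bayes factor computed by numerical integration
  (`bootstrap_group_comparison()`, `paired_comparison()`).
* **Classification** — multinomial naive Bayes, linear SVM, and random
  forest under bootstrap down-sampling with stratified 5-fold 80/20
  cross-validation; accuracy/kappa/specificity/precision/recall from
  pooled confusion counts and univariate ROC-AUC feature importance
  (`cross_validated_task()`, `roc_feature_importance()`).
* **Synthetic fixtures** — generators for lexicons, corpora with planted
  category signal, crowd rating tables, and embedding spaces, so
  everything above is testable offline (`make_lexicon_fixture()` and
  friends).

## Worked example

```r
library(grievlex)

lex <- new_lexicon(
  tibble::tibble(
    term        = c("fight", "bullet", "last resort", "warn", "pray"),
    category    = c("violence", "violence", "suicide", "threat", "god"),
    mean_rating = c(8.2, 7.4, 9.1, 7.0, 8.6),
    n_ratings   = c(9L, 8L, 7L, 11L, 10L)),
  variant = "threshold7",
  schema  = c("violence", "suicide", "threat", "god"))

doc <- tokenize_and_stem(
  "They warned us again and again. Fighting back is the last resort,
   but the bullets are ready and nobody prays for peace anymore.",
  doc_id = "example")

score_document(doc, lex, min_words = 10)
#> <grv_scores> 'example' (proportional): 6/23 tokens matched
#> violence  suicide   threat      god
#>   0.0870   0.0435   0.0435   0.0435
```

The document has 23 tokens; "warned", "Fighting", "bullets", and "prays"
match through their stems, and "last resort" matches as one two-token
suicide occurrence — hence violence 2/23 = 0.087 and 6 of 23 tokens
covered. The same pipeline scales to corpora via `build_dfm()`, which
returns a documents x (categories + no_match) matrix ready for the
comparison and classification functions, e.g.:

```r
compare_categories(dfm_manifestos, dfm_neutral, n_boot = 100, seed = 1)
#> one row per category: d, percentile interval, mean t, BF10, evidence label
bonferroni_threshold(22)$threshold_2sig
#> [1] 0.0023
```

A command-line front end is installed at `exec/grievlex` inside the
package directory (`file.path(find.package("grievlex"), "exec", "grievlex")`)
with subcommands `lexicon`, `score`, `build`, `compare`, and `classify`;
run it without arguments for usage.

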