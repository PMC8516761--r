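#' Snowball English (Porter2) word stemmer
#'
#' Stems English words with the Snowball English stemming algorithm, the
#' revision of Porter's original suffix-stripping algorithm used by most
#' word-count text analysis software. All lexicon terms and document tokens
#' in this package are matched in stem space, so the same stemmer is applied
#' on both sides.
#'
#' The implementation follows the published algorithm definition: marking of
#' consonantal \code{y}, the \code{R1}/\code{R2} regions (with the special
#' \code{gener-}, \code{commun-}, \code{arsen-} prefixes), the exceptional
#' word forms, and suffix steps 0 through 5. Multiword phrases should be
#' stemmed token-wise (see [tokenize_and_stem()]).
#'
#' @param words Character vector of words (single tokens, lowercase or not).
#' @return Character vector of stems, same length as `words`.
#' @examples
#' stem_words(c("friends", "friendly", "fighting", "bullets"))
#' @export
stem_words <- function(words) {
  if (length(words) == 0L) return(character(0))
  words <- tolower(words)
  # stem each unique token once; documents repeat tokens heavily
  uw <- unique(words)
  us <- vapply(uw, porter2_one, character(1), USE.NAMES = FALSE)
  us[match(words, uw)]
}

.p2_vowels <- c("a", "e", "i", "o", "u", "y")
.p2_doubles <- c("bb", "dd", "ff", "gg", "mm", "nn", "pp", "rr", "tt")
.p2_li_ending <- c("c", "d", "e", "g", "h", "k", "m", "n", "r", "t")

.p2_exceptions <- c(
  skis = "ski", skies = "sky", dying = "die", lying = "lie", tying = "tie",
  idly = "idl", gently = "gentl", ugly = "ugli", early = "earli",
  only = "onli", singly = "singl",
  sky = "sky", news = "news", howe = "howe", atlas = "atlas",
  cosmos = "cosmos", bias = "bias", andes = "andes"
)

.p2_exceptions_1a <- c("inning", "outing", "canning", "herring", "earring",
                       "proceed", "exceed", "succeed")

# step 2/3/4 suffix tables, ordered longest-first so the first match found
# is the longest match
.p2_step2 <- list(
  c("ization", "ize"), c("ational", "ate"), c("fulness", "ful"),
  c("ousness", "ous"), c("iveness", "ive"), c("tional", "tion"),
  c("biliti", "ble"), c("lessli", "less"), c("entli", "ent"),
  c("ation", "ate"), c("alism", "al"), c("aliti", "al"),
  c("ousli", "ous"), c("iviti", "ive"), c("fulli", "ful"),
  c("enci", "ence"), c("anci", "ance"), c("abli", "able"),
  c("izer", "ize"), c("ator", "ate"), c("alli", "al"),
  c("bli", "ble"), c("ogi", "og"), c("li", "")
)

.p2_step3 <- list(
  c("ational", "ate"), c("tional", "tion"), c("alize", "al"),
  c("icate", "ic"), c("iciti", "ic"), c("ative", ""),
  c("ical", "ic"), c("ness", ""), c("ful", "")
)

.p2_step4 <- c("ement", "ance", "ence", "able", "ible", "ment",
               "ant", "ent", "ism", "ate", "iti", "ous", "ive", "ize",
               "ion", "al", "er", "ic")

p2_is_vowel <- function(ch) ch %in% .p2_vowels

p2_ends_short_syllable <- function(w) {
  n <- nchar(w)
  if (n == 2L) {
    return(p2_is_vowel(substr(w, 1L, 1L)) && !p2_is_vowel(substr(w, 2L, 2L)))
  }
  if (n < 3L) return(FALSE)
  c3 <- substr(w, n - 2L, n - 2L)
  c2 <- substr(w, n - 1L, n - 1L)
  c1 <- substr(w, n, n)
  !p2_is_vowel(c3) && p2_is_vowel(c2) &&
    !p2_is_vowel(c1) && !(c1 %in% c("w", "x", "Y"))
}

porter2_one <- function(w) {
  if (startsWith(w, "'")) w <- substring(w, 2L)
  if (!is.na(ix <- match(w, names(.p2_exceptions)))) {
    return(unname(.p2_exceptions[ix]))
  }
  if (nchar(w) <= 2L) return(w)

  # mark y as consonant Y when word-initial or following a vowel
  ch <- strsplit(w, "", fixed = TRUE)[[1]]
  for (i in seq_along(ch)) {
    if (ch[i] == "y" && (i == 1L || ch[i - 1L] %in% .p2_vowels)) ch[i] <- "Y"
  }
  w <- paste(ch, collapse = "")
  n <- nchar(w)

  # R1: after the first non-vowel following a vowel (special prefixes fixed)
  p1 <- n + 1L
  if (startsWith(w, "gener") || startsWith(w, "arsen")) {
    p1 <- 6L
  } else if (startsWith(w, "commun")) {
    p1 <- 7L
  } else {
    for (i in 2:n) {
      if (!p2_is_vowel(substr(w, i, i)) && p2_is_vowel(substr(w, i - 1L, i - 1L))) {
        p1 <- i + 1L
        break
      }
    }
  }
  # R2: same construction continued inside R1
  p2 <- n + 1L
  if (p1 + 1L <= n) {
    for (i in (p1 + 1L):n) {
      if (!p2_is_vowel(substr(w, i, i)) && p2_is_vowel(substr(w, i - 1L, i - 1L))) {
        p2 <- i + 1L
        break
      }
    }
  }
  in_r1 <- function(w, m) nchar(w) - m + 1L >= p1
  in_r2 <- function(w, m) nchar(w) - m + 1L >= p2
  has_vowel <- function(w, upto) {
    upto >= 1L && any(strsplit(substr(w, 1L, upto), "", fixed = TRUE)[[1]] %in% .p2_vowels)
  }

  # step 0: possessive / quoted endings
  for (suf in c("'s'", "'s", "'")) {
    if (endsWith(w, suf)) {
      w <- substr(w, 1L, nchar(w) - nchar(suf))
      break
    }
  }

  # step 1a
  n <- nchar(w)
  if (endsWith(w, "sses")) {
    w <- substr(w, 1L, n - 2L)
  } else if (endsWith(w, "ied") || endsWith(w, "ies")) {
    w <- if (n > 4L) substr(w, 1L, n - 2L) else substr(w, 1L, n - 1L)
  } else if (endsWith(w, "us") || endsWith(w, "ss")) {
    # leave alone
  } else if (endsWith(w, "s")) {
    if (has_vowel(w, n - 2L)) w <- substr(w, 1L, n - 1L)
  }
  if (w %in% .p2_exceptions_1a) return(w)

  # step 1b
  n <- nchar(w)
  if (endsWith(w, "eedly")) {
    if (in_r1(w, 5L)) w <- substr(w, 1L, n - 3L)
  } else if (endsWith(w, "eed")) {
    if (in_r1(w, 3L)) w <- substr(w, 1L, n - 1L)
  } else {
    suf <- NULL
    for (s in c("ingly", "edly", "ing", "ed")) {
      if (endsWith(w, s)) { suf <- s; break }
    }
    if (!is.null(suf) && has_vowel(w, n - nchar(suf))) {
      w <- substr(w, 1L, n - nchar(suf))
      n <- nchar(w)
      if (endsWith(w, "at") || endsWith(w, "bl") || endsWith(w, "iz")) {
        w <- paste0(w, "e")
      } else if (n >= 2L && substr(w, n - 1L, n) %in% .p2_doubles) {
        w <- substr(w, 1L, n - 1L)
      } else if (p1 > n && p2_ends_short_syllable(w)) {
        w <- paste0(w, "e")
      }
    }
  }

  # step 1c: y -> i after a non-vowel that is not the first letter
  n <- nchar(w)
  last <- substr(w, n, n)
  if ((last == "y" || last == "Y") && n >= 3L &&
      !p2_is_vowel(substr(w, n - 1L, n - 1L))) {
    w <- paste0(substr(w, 1L, n - 1L), "i")
  }

  # step 2 (longest suffix, condition: in R1)
  for (rule in .p2_step2) {
    suf <- rule[1]
    if (endsWith(w, suf)) {
      if (in_r1(w, nchar(suf))) {
        n <- nchar(w)
        prev <- if (n > nchar(suf)) substr(w, n - nchar(suf), n - nchar(suf)) else ""
        if (suf == "ogi") {
          if (prev == "l") w <- paste0(substr(w, 1L, n - 3L), "og")
        } else if (suf == "li") {
          if (prev %in% .p2_li_ending) w <- substr(w, 1L, n - 2L)
        } else {
          w <- paste0(substr(w, 1L, n - nchar(suf)), rule[2])
        }
      }
      break
    }
  }

  # step 3 (longest suffix, condition: in R1; "ative" additionally in R2)
  for (rule in .p2_step3) {
    suf <- rule[1]
    if (endsWith(w, suf)) {
      if (in_r1(w, nchar(suf))) {
        if (suf == "ative") {
          if (in_r2(w, 5L)) w <- substr(w, 1L, nchar(w) - 5L)
        } else {
          w <- paste0(substr(w, 1L, nchar(w) - nchar(suf)), rule[2])
        }
      }
      break
    }
  }

  # step 4 (longest suffix, condition: in R2)
  for (suf in .p2_step4) {
    if (endsWith(w, suf)) {
      if (in_r2(w, nchar(suf))) {
        n <- nchar(w)
        if (suf == "ion") {
          prev <- if (n > 3L) substr(w, n - 3L, n - 3L) else ""
          if (prev == "s" || prev == "t") w <- substr(w, 1L, n - 3L)
        } else {
          w <- substr(w, 1L, n - nchar(suf))
        }
      }
      break
    }
  }

  # step 5
  n <- nchar(w)
  if (endsWith(w, "e")) {
    if (in_r2(w, 1L) ||
        (in_r1(w, 1L) && !p2_ends_short_syllable(substr(w, 1L, n - 1L)))) {
      w <- substr(w, 1L, n - 1L)
    }
  } else if (endsWith(w, "l")) {
    if (in_r2(w, 1L) && n >= 2L && substr(w, n - 1L, n - 1L) == "l") {
      w <- substr(w, 1L, n - 1L)
    }
  }

  chartr("Y", "y", w)
}

#' Stem a term that may contain internal spaces
#'
#' Multiword lexicon entries are stemmed token by token so that phrase
#' matching operates entirely in stem space.
#'
#' @param terms Character vector of terms; tokens separated by single spaces.
#' @return Character vector of token-wise stemmed terms.
#' @export
stem_terms <- function(terms) {
  if (length(terms) == 0L) return(character(0))
  parts <- strsplit(tolower(terms), " ", fixed = TRUE)
  vapply(parts, function(p) paste(stem_words(p[nzchar(p)]), collapse = " "),
         character(1))
}
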