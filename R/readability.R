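# Readability indices from explicit token, sentence and syllable counts.
#
# Four classical indices are computed from one pass of tokenisation:
#   FRE = 206.835 - 1.015*(words/sentences) - 84.6*(syllables/words)
#   FKG = 0.39*(words/sentences) + 11.8*(syllables/words) - 15.59
#   ARI = 4.71*(characters/words) + 0.5*(words/sentences) - 21.43
#   GFI = 0.4*[ words/sentences + 100*(complex words/words) ]
# Scores are reported unclamped: an FRE outside [0, 100] signals degenerate
# text rather than being hidden.

.vowel_group_rx <- "[aeiouy]+"

#' Count syllables heuristically
#'
#' Deterministic dictionary-free syllable counter used by all indices:
#' maximal vowel groups (a, e, i, o, u, y) are counted; a silent terminal "e"
#' is subtracted unless the word ends in consonant + "le"; terminal "-es" /
#' "-ed" endings are silent unless the preceding consonant requires the vowel
#' (sibilant before "-es", t/d before "-ed"); an "ia" hiatus counts as two
#' syllables except inside word-final -cial/-tial/-sian type endings; the
#' count is floored at one.
#'
#' @param words Character vector of single tokens, each containing at least
#'   one letter.
#' @return Integer vector of syllable counts (all >= 1).
#' @export
#' @examples
#' count_syllables(c("cat", "stroke", "association"))
count_syllables <- function(words) {
  stopifnot(is.character(words))
  if (length(words) == 0L) return(integer(0))
  w <- tolower(stringr::str_remove_all(words, "[^\\p{L}]"))
  if (any(!nzchar(w))) {
    pil_abort("count_syllables: token without letters", "pil_invalid_input")
  }
  n <- stringr::str_count(w, .vowel_group_rx)
  # silent terminal e, except consonant + "le" ("table", "little")
  plain_e <- stringr::str_detect(w, "e$") &
    !stringr::str_detect(w, "[^aeiouy]le$") &
    !stringr::str_detect(w, "(es|ed)$")
  n <- n - as.integer(plain_e)
  # terminal -es/-ed: silent unless the preceding consonant needs the vowel
  es <- stringr::str_detect(w, "[^aeiouy]es$")
  ed <- stringr::str_detect(w, "[^aeiouy]ed$")
  es_keep <- stringr::str_detect(w, "[sxzcg]es$") |
    stringr::str_detect(w, "(ch|sh)es$")
  ed_keep <- stringr::str_detect(w, "[td]ed$")
  n <- n - as.integer(es & !es_keep) - as.integer(ed & !ed_keep)
  # "ia" hiatus ("association", "trial") splits a vowel group in two, except
  # in fused word-final endings like -cial, -tial, -sian, -giant-less -xial
  hiatus <- stringr::str_count(w, "ia") -
    as.integer(stringr::str_detect(w, "[cstgx]ia[ln]s?$"))
  n <- n + pmax(hiatus, 0L)
  pmax(as.integer(n), 1L)
}

new_text_statistics <- function(n_sentences, n_words, n_syllables,
                                n_characters, n_complex_words) {
  stats <- list(
    n_sentences = as.integer(n_sentences),
    n_words = as.integer(n_words),
    n_syllables = as.integer(n_syllables),
    n_characters = as.integer(n_characters),
    n_complex_words = as.integer(n_complex_words)
  )
  structure(stats, class = "text_statistics")
}

#' @export
print.text_statistics <- function(x, ...) {
  cat(sprintf(
    "Text statistics: %d sentences, %d words, %d syllables, %d characters, %d complex words\n",
    x$n_sentences, x$n_words, x$n_syllables, x$n_characters, x$n_complex_words
  ))
  invisible(x)
}

#' Tokenise standardised text into counting statistics
#'
#' One pass producing every quantity the four indices consume. Sentences are
#' segments terminated by `.`, `!` or `?`; a heading line ending `:` counts as
#' one sentence (standardisation guarantees headings carry punctuation).
#' Words are whitespace tokens stripped of surrounding punctuation and dropped
#' if letterless. Characters are the alphanumeric characters of words.
#' Complex words (Gunning Fog) have >= 3 heuristic syllables, excluding words
#' capitalised mid-sentence (a proxy for proper nouns) and words reaching
#' three syllables only through an "-es"/"-ed" inflection; hyphenated
#' compounds are split and each part assessed.
#'
#' @param text Standardised text (character scalar) with at least one word.
#' @return A `text_statistics` object with fields `n_sentences`, `n_words`,
#'   `n_syllables`, `n_characters`, `n_complex_words`.
#' @export
#' @examples
#' tokenise("The cat sat on the mat.")
tokenise <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  # heading colons at end of line act as sentence terminators
  txt <- stringr::str_replace_all(text, ":(?=\n|$)", ".")
  segments <- stringr::str_split_1(txt, "[.!?]+")
  has_word <- stringr::str_detect(segments, "\\p{L}")
  n_sentences <- max(sum(has_word), 1L)

  words_per_segment <- lapply(segments[has_word], function(seg) {
    toks <- stringr::str_split_1(stringr::str_trim(seg), "\\s+")
    toks <- stringr::str_remove_all(toks, "^[^\\p{L}\\p{N}]+|[^\\p{L}\\p{N}]+$")
    toks[stringr::str_detect(toks, "\\p{L}")]
  })
  words <- unlist(words_per_segment)
  if (length(words) == 0L) {
    pil_abort("tokenise: text contains no words", "pil_invalid_input")
  }

  n_characters <- sum(stringr::str_count(words, "[\\p{L}\\p{N}]"))
  syl <- syllables_of(words)
  n_syllables <- sum(syl)

  # complex-word rule needs sentence position for the proper-noun proxy
  first_in_sentence <- unlist(lapply(words_per_segment, function(ws) {
    if (length(ws) == 0L) logical(0) else c(TRUE, rep(FALSE, length(ws) - 1L))
  }))
  is_complex <- vapply(seq_along(words), function(i) {
    word_is_complex(words[i], mid_sentence_cap = !first_in_sentence[i])
  }, logical(1))

  new_text_statistics(
    n_sentences = n_sentences,
    n_words = length(words),
    n_syllables = n_syllables,
    n_characters = n_characters,
    n_complex_words = sum(is_complex)
  )
}

# syllable counts for a word vector, memoised over unique tokens
syllables_of <- function(words) {
  u <- unique(words)
  count_syllables(u)[match(words, u)]
}

# Gunning Fog complexity for one token; hyphenated compounds are split and
# each part assessed on its own
word_is_complex <- function(word, mid_sentence_cap) {
  parts <- stringr::str_split_1(word, "-")
  parts <- parts[stringr::str_detect(parts, "\\p{L}")]
  if (length(parts) == 0L) return(FALSE)
  any(vapply(parts, function(p) {
    if (mid_sentence_cap && stringr::str_detect(p, "^\\p{Lu}")) return(FALSE)
    s <- count_syllables(p)
    if (s < 3L) return(FALSE)
    # exclude words that reach 3 syllables only through -es/-ed inflection
    stem <- stringr::str_remove(p, "(es|ed)$")
    if (stem != p && nzchar(stringr::str_remove_all(stem, "[^\\p{L}]")) &&
        count_syllables(stem) < 3L) {
      return(FALSE)
    }
    TRUE
  }, logical(1)))
}

check_stats <- function(stats) {
  if (!inherits(stats, "text_statistics")) {
    stopifnot(is.list(stats),
              all(c("n_sentences", "n_words") %in% names(stats)))
  }
  if (stats$n_sentences < 1L || stats$n_words < 1L) {
    pil_abort("readability formulas need >= 1 sentence and >= 1 word",
              "pil_invalid_input")
  }
  stats
}

#' Flesch Reading Ease
#'
#' `206.835 - 1.015 * (words/sentences) - 84.6 * (syllables/words)`. Higher is
#' easier; the conventional band is 0-100 but values are reported unclamped.
#'
#' @param stats A `text_statistics` object (or compatible list).
#' @return Numeric score.
#' @export
flesch_reading_ease <- function(stats) {
  s <- check_stats(stats)
  206.835 - 1.015 * (s$n_words / s$n_sentences) -
    84.6 * (s$n_syllables / s$n_words)
}

#' Flesch-Kincaid Grade
#'
#' `0.39 * (words/sentences) + 11.8 * (syllables/words) - 15.59`: the U.S.
#' school grade needed to comprehend the text. Reported unclamped.
#'
#' @inheritParams flesch_reading_ease
#' @return Numeric grade level.
#' @export
flesch_kincaid_grade <- function(stats) {
  s <- check_stats(stats)
  0.39 * (s$n_words / s$n_sentences) +
    11.8 * (s$n_syllables / s$n_words) - 15.59
}

#' Automated Readability Index
#'
#' `4.71 * (characters/words) + 0.5 * (words/sentences) - 21.43`, with
#' characters counted as alphanumeric characters of words.
#'
#' @inheritParams flesch_reading_ease
#' @return Numeric grade level.
#' @export
automated_readability_index <- function(stats) {
  s <- check_stats(stats)
  4.71 * (s$n_characters / s$n_words) +
    0.5 * (s$n_words / s$n_sentences) - 21.43
}

#' Gunning Fog Index
#'
#' `0.4 * [ words/sentences + 100 * (complex words/words) ]`: estimated years
#' of formal education needed for understanding.
#'
#' @inheritParams flesch_reading_ease
#' @return Numeric years-of-education score.
#' @export
gunning_fog <- function(stats) {
  s <- check_stats(stats)
  0.4 * (s$n_words / s$n_sentences +
           100 * (s$n_complex_words / s$n_words))
}

#' Full readability profile of a standardised text
#'
#' Tokenises once and applies all four indices. Values are rounded to two
#' decimals for reporting.
#'
#' @param text Standardised text (character scalar).
#' @return A one-row tibble with columns `fkg`, `fre`, `ari`, `gfi`.
#' @export
#' @examples
#' readability_profile("Driving is banned for one month. Ask your doctor.")
readability_profile <- function(text) {
  stats <- tokenise(text)
  tibble::tibble(
    fkg = round_half_up(flesch_kincaid_grade(stats), 2),
    fre = round_half_up(flesch_reading_ease(stats), 2),
    ari = round_half_up(automated_readability_index(stats), 2),
    gfi = round_half_up(gunning_fog(stats), 2)
  )
}
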