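# Seeded synthetic corpus generation.
#
# The generator emulates the *shape* of standardisable patient leaflets —
# controllable sentence length and syllable mix, bullet lists, headings (some
# interrogative), inline citations, emojis, a flattened label-value table,
# line-break hyphenation artefacts — so every standardiser rule and the whole
# readability engine can be exercised without any external corpus. It does
# not imitate real leaflet prose: sentences are grammatically meaningless
# draws from a built-in vocabulary stratified by syllable count, which is
# what makes target syllable ratios constructible without a dictionary.

.words_1syl <- c(
  "the", "and", "you", "must", "not", "drive", "car", "road", "stroke",
  "month", "one", "if", "your", "tell", "them", "ask", "rest", "safe",
  "signs", "first", "check", "plan", "stop", "wait", "talk", "team", "test",
  "form", "rules", "law", "risk", "time", "week", "help", "care", "home",
  "walk", "bus", "train", "clear", "stay", "call", "nurse", "speech",
  "street", "sight", "brain", "blood", "health"
)
.words_2syl <- c(
  "doctor", "driving", "after", "over", "advice", "licence", "patient",
  "seizure", "contact", "question", "vision", "money", "leaflet", "letter",
  "member", "little", "always", "never", "again", "also", "any", "body",
  "early", "better", "travel", "update", "journey", "support"
)
.words_3syl <- c(
  "hospital", "medical", "notify", "assessment", "decision", "condition",
  "important", "remember", "accident", "family", "holiday", "understand",
  "insurance", "government", "relative", "recommend"
)

.plain_headings <- c("Key facts", "Driving rules", "Your licence",
                     "Next steps", "Insurance advice", "Getting help",
                     "Money and travel")
.question_headings <- c("What happens next", "Can I drive now",
                        "When should I call", "How do I tell them",
                        "Should I stop driving")
.emojis <- c("\U0001F697", "\U0001F44D", "✅", "⚠️")

#' Recipe for a synthetic leaflet corpus
#'
#' Defaults describe a leaflet-like corpus: eight leaflets of sixty prose
#' sentences averaging fourteen words at 1.5 syllables per word, with a third
#' of sentences rendered as bullet items, a heading every five sentences, and
#' a flattened label-value table. Targets for sentence length and syllable
#' ratio apply to prose and bullet sentences; headings are short
#' colon-terminated lines and dilute the realised averages when enabled.
#'
#' @param n_leaflets Number of leaflets (>= 1).
#' @param mean_sentence_length Target mean words per sentence (> 0).
#' @param syllable_ratio Target syllables per word, in \[1, 3\] (the built-in
#'   vocabulary spans one to three syllables).
#' @param bullet_fraction Fraction of sentences rendered as bullet items.
#' @param heading_every_k_sentences Insert a heading every k sentences.
#' @param include_table Append a flattened label-value table.
#' @param sentences_per_leaflet Prose sentences per leaflet.
#' @param seed Integer seed; generation is deterministic given the recipe.
#' @return A `corpus_recipe` list.
#' @export
corpus_recipe <- function(n_leaflets = 8, mean_sentence_length = 14,
                          syllable_ratio = 1.5, bullet_fraction = 0.3,
                          heading_every_k_sentences = 5, include_table = TRUE,
                          sentences_per_leaflet = 60, seed = 1L) {
  if (syllable_ratio < 1) {
    pil_abort("syllable_ratio < 1 is unreachable (every word has >= 1 syllable)",
              "pil_invalid_input")
  }
  if (syllable_ratio > 3) {
    pil_abort("syllable_ratio > 3 is unreachable with the built-in vocabulary",
              "pil_invalid_input")
  }
  stopifnot(n_leaflets >= 1, mean_sentence_length > 0,
            bullet_fraction >= 0, bullet_fraction <= 1,
            heading_every_k_sentences >= 1, sentences_per_leaflet >= 1)
  structure(list(
    n_leaflets = as.integer(n_leaflets),
    mean_sentence_length = mean_sentence_length,
    syllable_ratio = syllable_ratio,
    bullet_fraction = bullet_fraction,
    heading_every_k_sentences = as.integer(heading_every_k_sentences),
    include_table = isTRUE(include_table),
    sentences_per_leaflet = as.integer(sentences_per_leaflet),
    seed = as.integer(seed)
  ), class = "corpus_recipe")
}

# mixture over 1/2/3-syllable strata hitting the target expected ratio
syllable_mixture <- function(ratio) {
  p2 <- min(0.2, ratio - 1)
  p3 <- (ratio - 1 - p2) / 2
  c(1 - p2 - p3, p2, p3)
}

draw_sentence <- function(n_words, mix) {
  strata <- sample.int(3L, n_words, replace = TRUE, prob = mix)
  words <- vapply(strata, function(s) {
    pool <- switch(s, .words_1syl, .words_2syl, .words_3syl)
    pool[sample.int(length(pool), 1L)]
  }, character(1))
  words[1] <- paste0(toupper(substr(words[1], 1, 1)),
                     substr(words[1], 2, nchar(words[1])))
  words
}

#' Generate a raw synthetic leaflet corpus
#'
#' Deterministic given the recipe's seed. Raw bodies contain bullet markers,
#' headings without punctuation (some interrogative), inline bracketed
#' citations, emojis, line-break hyphenation artefacts, doubled spaces, extra
#' blank lines, an optional flattened table and a terminal references block —
#' so that every standardisation rule fires on a full-featured recipe.
#'
#' @param recipe A [corpus_recipe()].
#' @return Tibble with columns `leaflet_id`, `body` (raw text).
#' @export
generate_leaflet_text <- function(recipe) {
  stopifnot(inherits(recipe, "corpus_recipe"))
  mix <- syllable_mixture(recipe$syllable_ratio)
  withr::with_seed(recipe$seed, {
    bodies <- vapply(seq_len(recipe$n_leaflets), function(i) {
      one_leaflet_body(recipe, mix)
    }, character(1))
  })
  tibble::tibble(
    leaflet_id = sprintf("leaflet_%03d", seq_len(recipe$n_leaflets)),
    body = bodies
  )
}

one_leaflet_body <- function(recipe, mix) {
  lines <- character(0)
  citation_n <- 0L
  bullet_markers <- c("• ", "- ", "* ")
  for (s in seq_len(recipe$sentences_per_leaflet)) {
    if ((s - 1L) %% recipe$heading_every_k_sentences == 0L &&
        recipe$heading_every_k_sentences <= recipe$sentences_per_leaflet) {
      pool <- if (stats::runif(1) < 0.5) .plain_headings else .question_headings
      lines <- c(lines, "", pool[sample.int(length(pool), 1L)])
    }
    n_words <- max(3L, stats::rpois(1L, recipe$mean_sentence_length))
    words <- draw_sentence(n_words, mix)
    sentence <- paste(words, collapse = " ")
    if (stats::runif(1) < 0.15) {
      citation_n <- citation_n + 1L
      sentence <- paste0(sentence, " [", citation_n, "]")
    }
    if (stats::runif(1) < recipe$bullet_fraction) {
      marker <- bullet_markers[sample.int(3L, 1L)]
      lines <- c(lines, paste0(marker, sentence))
    } else {
      sentence <- paste0(sentence, ".")
      if (stats::runif(1) < 0.05) {
        sentence <- paste0(sentence, " ", .emojis[sample.int(4L, 1L)])
      }
      if (stats::runif(1) < 0.05) sentence <- hyphen_break(sentence)
      if (stats::runif(1) < 0.05) {
        sentence <- sub(" ", "  ", sentence, fixed = TRUE)
      }
      lines <- c(lines, sentence)
    }
  }
  if (recipe$include_table) {
    pairs <- tibble::tibble(
      label = c("Vehicle", "Minimum time off driving", "Form"),
      value = c("Car or motorcycle", "1 month", "STR1V")
    )
    lines <- c(lines, "", "", flatten_table(pairs))
  }
  lines <- c(lines, "", "References:", "1. Driving guidance document.",
             "2. Licensing agency website.")
  paste(lines, collapse = "\n")
}

# simulate a line-break hyphenation extraction artefact on a long word
hyphen_break <- function(sentence) {
  toks <- stringr::str_split_1(sentence, " ")
  long <- which(stringr::str_detect(toks, "^\\p{L}{6,}$") &
                  seq_along(toks) > 1)
  if (length(long) == 0L) return(sentence)
  i <- long[sample.int(length(long), 1L)]
  w <- toks[i]
  cut <- nchar(w) %/% 2L
  toks[i] <- paste0(substr(w, 1, cut), "-\n", substr(w, cut + 1L, nchar(w)))
  paste(toks, collapse = " ")
}

#' Summary statistics of a standardised corpus
#'
#' Mean words per sentence and syllables per word over the corpus, using the
#' package tokeniser — the quantities the corpus recipe targets.
#'
#' @param corpus Tibble with a `body` column of standardised texts.
#' @return List with `mean_sentence_length` and `syllable_ratio`.
#' @export
corpus_statistics <- function(corpus) {
  stats_list <- lapply(corpus$body, tokenise)
  words <- sum(vapply(stats_list, `[[`, integer(1), "n_words"))
  sents <- sum(vapply(stats_list, `[[`, integer(1), "n_sentences"))
  syls <- sum(vapply(stats_list, `[[`, integer(1), "n_syllables"))
  list(mean_sentence_length = words / sents, syllable_ratio = syls / words)
}

#' Recipe for a random instrument score table
#'
#' @param n_leaflets Number of leaflets (>= 2).
#' @param seed Integer seed.
#' @return A `score_table_recipe` list.
#' @export
score_table_recipe <- function(n_leaflets = 8, seed = 1L) {
  stopifnot(n_leaflets >= 2)
  structure(list(n_leaflets = as.integer(n_leaflets),
                 seed = as.integer(seed)),
            class = "score_table_recipe")
}

#' Generate a random raw score table
#'
#' Uniform sampling within instrument scale bounds (DISCERN integer in 16-80,
#' PEMAT percentages in 0-100, misinformation subdomains in \{0,1,2\} summed
#' to the total, references in \{0,1,2\}) and plausible readability ranges.
#' Deterministic per seed; the output always passes score-table validation.
#'
#' @param recipe A [score_table_recipe()].
#' @return A validated raw score table tibble.
#' @export
generate_score_table <- function(recipe) {
  stopifnot(inherits(recipe, "score_table_recipe"))
  n <- recipe$n_leaflets
  withr::with_seed(recipe$seed, {
    sub <- matrix(sample(0:2, 3L * n, replace = TRUE), ncol = 3L)
    tab <- tibble::tibble(
      leaflet_id = sprintf("leaflet_%03d", seq_len(n)),
      word_count = sample(300:1400, n, replace = TRUE),
      fkg = round(stats::runif(n, 5, 13), 2),
      fre = round(stats::runif(n, 30, 80), 2),
      ari = round(stats::runif(n, 5, 13), 2),
      gfi = round(stats::runif(n, 6, 13), 1),
      discern = sample(16:80, n, replace = TRUE),
      pemat_u = round(stats::runif(n, 0, 100), 1),
      pemat_a = round(stats::runif(n, 0, 100), 1),
      misinfo_total = misinformation_total(sub[, 1], sub[, 2], sub[, 3]),
      references = sample(0:2, n, replace = TRUE)
    )
  })
  validate_score_table(tab, where = "generated score table")
}
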