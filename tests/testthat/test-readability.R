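test_that("syllable counts match dictionary-checked examples and stay >= 1", {
  expect_identical(count_syllables(c("cat", "stroke", "association")),
                   c(1L, 1L, 5L))
  expect_identical(count_syllables(c("table", "little")), c(2L, 2L))
  expect_identical(count_syllables(c("walked", "wanted", "classes")),
                   c(1L, 2L, 2L))
  expect_error(count_syllables("123"), class = "pil_invalid_input")
  vocab <- c("a", "I", "queue", "rhythm", "insurance", "trial", "special")
  expect_true(all(count_syllables(vocab) >= 1L))
})

test_that("tokenise reproduces hand counts and its internal invariants", {
  s <- tokenise("Driving is banned for one month. Ask your doctor.")
  expect_equal(s$n_sentences, 2L)
  expect_equal(s$n_words, 9L)

  s2 <- tokenise("The cat sat on the mat.")
  expect_equal(s2$n_words, 6L)
  expect_equal(s2$n_syllables, 6L)
  expect_equal(s2$n_characters, 17L)

  s3 <- tokenise("Hi.")
  expect_equal(s3$n_sentences, 1L)
  expect_equal(s3$n_words, 1L)

  # a heading line ending ':' counts as one sentence
  s4 <- tokenise("Key facts:\nDo not drive.")
  expect_equal(s4$n_sentences, 2L)

  expect_error(tokenise("12 34 ..."), class = "pil_invalid_input")

  for (txt in c("Remember your important insurance assessment.",
                "Tell the hospital. Notify your family doctor [sic].")) {
    st <- tokenise(txt)
    expect_lte(st$n_complex_words, st$n_words)
    expect_gte(st$n_syllables, st$n_words)
    expect_gte(st$n_characters, st$n_words)
  }
})

test_that("complex-word rule applies the proper-noun and inflection exclusions", {
  # 'Peterborough' mid-sentence is capitalised -> excluded; 'hospital' counts
  s <- tokenise("We went to the Peterborough hospital.")
  expect_equal(s$n_complex_words, 1L)
  # sentence-initial capitalised word is assessed normally
  expect_equal(tokenise("Hospital visits are short.")$n_complex_words, 1L)
  # hyphenated compound of two short parts is not complex
  expect_equal(tokenise("A well-known risk.")$n_complex_words, 0L)
})

test_that("the four formulas match their closed-form plug-ins", {
  expect_equal(flesch_reading_ease(stats_of(1, 1, 1)), 121.22)
  expect_equal(flesch_reading_ease(stats_of(1, 10, 10)), 112.085)
  expect_equal(flesch_kincaid_grade(stats_of(10, 100, 150)), 6.01)
  expect_equal(flesch_kincaid_grade(stats_of(1, 1, 1)), -3.4)
  expect_equal(
    automated_readability_index(stats_of(1, 10, 10, n_characters = 40)), 2.41)
  expect_equal(
    automated_readability_index(stats_of(1, 20, 20, n_characters = 100)),
    12.12)
  expect_equal(gunning_fog(stats_of(1, 10, n_complex_words = 2)), 12.0)
  expect_equal(gunning_fog(stats_of(1, 8, n_complex_words = 0)), 3.2)
  expect_error(flesch_reading_ease(stats_of(0, 5)),
               class = "pil_invalid_input")
})

test_that("formula evaluation is pure and the profile is finite", {
  s <- stats_of(3, 40, 60, 170, 5)
  expect_identical(flesch_kincaid_grade(s), flesch_kincaid_grade(s))
  p <- readability_profile(
    "Driving is banned for one month. Ask your doctor about insurance.")
  expect_true(all(vapply(p, is.finite, logical(1))))
})

test_that("longer sentences raise grade-level indices and lower reading ease", {
  base <- generate_leaflet_text(corpus_recipe(
    n_leaflets = 1, mean_sentence_length = 8, syllable_ratio = 1.4,
    bullet_fraction = 0, heading_every_k_sentences = 1000,
    include_table = FALSE, sentences_per_leaflet = 40, seed = 9))
  body <- standardise_leaflet("s", base$body)$body
  ps <- readability_profile(body)
  pl <- readability_profile(merge_sentence_pairs(body))
  # words and syllables are shared; only sentence segmentation differs
  expect_equal(tokenise(merge_sentence_pairs(body))$n_syllables,
               tokenise(body)$n_syllables)
  expect_gt(pl$fkg, ps$fkg)
  expect_gt(pl$ari, ps$ari)
  expect_gt(pl$gfi, ps$gfi)
  expect_lt(pl$fre, ps$fre)
})

test_that("both routes to each index agree on a small corpus", {
  corpus <- generate_leaflet_text(corpus_recipe(
    n_leaflets = 10, bullet_fraction = 0.3, heading_every_k_sentences = 1000,
    include_table = FALSE, sentences_per_leaflet = 25, seed = 11))
  std <- standardise_corpus(corpus)
  for (i in seq_len(nrow(std))) {
    mine <- readability_profile(std$body[i])
    ref <- oracle_indices(std$body[i])
    expect_lt(abs(mine$fkg - ref$fkg), 0.6)
    expect_lt(abs(mine$ari - ref$ari), 0.6)
    expect_lt(abs(mine$gfi - ref$gfi), 0.6)
    expect_lt(abs(mine$fre - ref$fre), 3)
  }
})
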