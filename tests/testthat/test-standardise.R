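test_that("citations, reference blocks and decorative symbols are stripped", {
  expect_equal(strip_citations_and_symbols("Do not drive [1]. See GOV.UK."),
               "Do not drive. See GOV.UK.")
  expect_equal(strip_citations_and_symbols("Stay safe \U0001F697"),
               "Stay safe")
  expect_equal(strip_citations_and_symbols("plain sentence."),
               "plain sentence.")
  expect_equal(strip_citations_and_symbols("See advice [2,3] and [4-6]."),
               "See advice and.")
  # terminal reference block dropped from its heading onwards
  out <- strip_citations_and_symbols(
    "Drive safely.\nReferences:\n1. Some guidance.\n2. A website.")
  expect_equal(out, "Drive safely.")
  expect_equal(strip_citations_and_symbols(""), "")
})

test_that("bullet items become left-aligned complete sentences", {
  expect_equal(normalise_bullets("• Do not drive for one month"),
               "Do not drive for one month.")
  expect_equal(normalise_bullets("- Tell your insurer."),
               "Tell your insurer.")
  expect_equal(normalise_bullets("* Ask your GP\n* Rest well"),
               "Ask your GP.\nRest well.")
  # non-list hyphens untouched
  expect_equal(normalise_bullets("well-known risk stays."),
               "well-known risk stays.")
})

test_that("headings gain a colon, interrogatives a question mark, never both", {
  expect_equal(normalise_headings("Key facts"), "Key facts:")
  expect_equal(normalise_headings("Can I drive after a TIA"),
               "Can I drive after a TIA?")
  expect_equal(normalise_headings("When can I drive?"), "When can I drive?")
  expect_equal(normalise_headings("What to do next:"), "What to do next?")
  # nine-token lines and punctuated lines are not headings
  long_line <- "one two three four five six seven eight nine"
  expect_equal(normalise_headings(long_line), long_line)
  expect_equal(normalise_headings("A full sentence."), "A full sentence.")
})

test_that("tables flatten to label-value sentences in order", {
  rows <- data.frame(
    label = c("Vehicle", "Minimum time off driving"),
    value = c("Car or motorcycle", "1 month")
  )
  expect_equal(flatten_table(rows),
               "Vehicle: Car or motorcycle. Minimum time off driving: 1 month.")
  expect_equal(flatten_table(data.frame(label = "Form", value = "STR1V")),
               "Form: STR1V.")
  expect_equal(flatten_table(list()), "")
  expect_error(flatten_table(data.frame(label = "", value = "x")),
               class = "pil_invalid_input")
})

test_that("whitespace collapses and line-break hyphenation rejoins", {
  expect_equal(normalise_whitespace_and_hyphenation("driv-\ning licence"),
               "driving licence")
  expect_equal(normalise_whitespace_and_hyphenation("a  b\t c"), "a b c")
  expect_equal(normalise_whitespace_and_hyphenation("well-known risk"),
               "well-known risk")
  expect_equal(normalise_whitespace_and_hyphenation("a.\n\n\n\nb."),
               "a.\n\nb.")
})

test_that("standardise_leaflet composes the passes and satisfies the format", {
  raw <- paste(
    "Key facts",
    "• Do not drive for one month",
    "• Tell your insurer",
    "",
    "Can I drive after a TIA",
    "You must wait and ask your doctor [1]. \U0001F697",
    "Your driving assess-",
    "ment may be needed.",
    sep = "\n"
  )
  out <- standardise_leaflet("demo", raw)
  expect_equal(standardised_violations(out$body), character(0))
  expect_match(out$body, "Key facts:", fixed = TRUE)
  expect_match(out$body, "Can I drive after a TIA?", fixed = TRUE)
  expect_match(out$body, "Do not drive for one month.", fixed = TRUE)
  expect_match(out$body, "assessment", fixed = TRUE)
  expect_false(grepl("[1]", out$body, fixed = TRUE))
  expect_equal(out$word_count,
               length(strsplit(out$body, "\\s+")[[1]]))
  # idempotence and degenerate input
  expect_identical(standardise_leaflet("demo", out$body)$body, out$body)
  expect_error(standardise_leaflet("demo", "  \n "),
               class = "pil_empty_leaflet")
})

test_that("standardisation is idempotent, lexically conservative and
           format-conformant on a seeded synthetic corpus", {
  recipe <- corpus_recipe(n_leaflets = 30, seed = 42, bullet_fraction = 0.4,
                          sentences_per_leaflet = 20)
  corpus <- generate_leaflet_text(recipe)
  std <- standardise_corpus(corpus)
  for (i in seq_len(nrow(std))) {
    expect_equal(standardised_violations(std$body[i]), character(0))
    expect_identical(standardise_leaflet(std$leaflet_id[i], std$body[i])$body,
                     std$body[i])
    out_toks <- lexical_tokens(std$body[i])
    in_toks <- lexical_tokens(corpus$body[i])
    expect_true(is_subsequence(out_toks, in_toks))
  }
})
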