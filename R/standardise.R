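# Structure-only text standardisation.
#
# Leaflets arrive as plain text with bullets, headings, inline citations,
# emojis and extraction artefacts. The standardiser applies four ordered,
# purely structural passes so any leaflet is parsed consistently by the
# readability engine: strip citations/symbols -> normalise bullets ->
# normalise headings -> normalise whitespace/hyphenation. No paraphrasing or
# lexical edits: every surviving alphabetic token of the output appears in the
# input, in order.

# bullet markers recognised at the start of a list line
.bullet_rx <- "^[ \t]*[•▪◦‣·*+-][ \t]+"

# inline bracketed numeric citation, e.g. [1], [2,3], [4-6]
.citation_rx <- "[ \t]*\\[\\s*\\d+(\\s*[-–,;]\\s*\\d+)*\\s*\\]"

# characters kept by the conservative allow-list: letters, digits, whitespace,
# standard punctuation, currency signs
.allowlist_rx <- "[^\\p{L}\\p{N}\\s.,;:!?'\"()\\[\\]%/&@+=£$€–—-]"

# WH-words and auxiliaries that mark an interrogative heading
.interrogative_starters <- c(
  "what", "when", "where", "who", "whom", "whose", "why", "which", "how",
  "can", "could", "do", "does", "did", "is", "are", "was", "were", "will",
  "would", "should", "shall", "may", "might", "must"
)

#' Remove citations, reference blocks and decorative symbols
#'
#' Deletes inline bracketed numeric citations (`[1]`, `[2,3]`, `[4-6]`), a
#' terminal reference block introduced by a "References"/"Sources" style
#' heading, and any character outside a conservative allow-list (letters,
#' digits, standard punctuation, currency signs, whitespace) — emojis and
#' decorative symbols in particular. Wording is otherwise untouched.
#'
#' @param text Character scalar of raw leaflet text (may be empty).
#' @return The cleaned text.
#' @export
#' @examples
#' strip_citations_and_symbols("Do not drive [1]. See GOV.UK.")
#' strip_citations_and_symbols("Stay safe \U0001F697")
strip_citations_and_symbols <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text)) return(text)
  lines <- stringr::str_split_1(text, "\n")
  # drop a terminal block introduced by a references-type heading
  ref_head <- stringr::str_detect(
    lines, stringr::regex("^[ \t]*(references?|sources?)[ \t]*:?[ \t]*$",
                          ignore_case = TRUE)
  )
  if (any(ref_head)) lines <- lines[seq_len(which(ref_head)[1] - 1L)]
  lines <- stringr::str_remove_all(lines, .citation_rx)
  # protect a leading list marker: it belongs to the bullet pass, which runs
  # after this one; only mid-line decorative bullets are stripped here
  marker <- stringr::str_extract(lines, .bullet_rx)
  marker[is.na(marker)] <- ""
  rest <- stringr::str_sub(lines, nchar(marker) + 1L)
  rest <- stringr::str_remove_all(rest, .allowlist_rx)
  lines <- paste0(marker, rest)
  lines <- stringr::str_remove(lines, "[ \t]+$")
  paste(lines, collapse = "\n")
}

#' Normalise bullet lists
#'
#' Removes leading bullet/hyphen/asterisk markers (rendering list items as
#' left-aligned lines) and appends a full stop to any list line lacking
#' terminal sentence punctuation (`.`, `!`, `?`), so list items are parsed as
#' complete sentences.
#'
#' @param text Character scalar.
#' @return Text with list lines normalised.
#' @export
#' @examples
#' normalise_bullets("• Do not drive for one month")
#' normalise_bullets("- Tell your insurer.")
normalise_bullets <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text)) return(text)
  lines <- stringr::str_split_1(text, "\n")
  is_item <- stringr::str_detect(lines, .bullet_rx)
  lines[is_item] <- stringr::str_remove(lines[is_item], .bullet_rx)
  lines[is_item] <- stringr::str_remove(lines[is_item], "[ \t]+$")
  needs_stop <- is_item & nzchar(lines) &
    !stringr::str_detect(lines, "[.!?]$")
  lines[needs_stop] <- paste0(lines[needs_stop], ".")
  paste(lines, collapse = "\n")
}

# heading convention: a short line (<= 8 whitespace tokens) without terminal
# sentence punctuation, not a list item, not a hyphen-broken line fragment
is_heading_line <- function(lines) {
  tok_n <- stringr::str_count(stringr::str_trim(lines), "\\S+")
  nzchar(stringr::str_trim(lines)) &
    tok_n <= 8L &
    !stringr::str_detect(lines, "[.!?]$") &
    !stringr::str_detect(lines, .bullet_rx) &
    !stringr::str_detect(lines, "-$")
}

is_interrogative <- function(lines) {
  first <- tolower(stringr::str_extract(stringr::str_trim(lines), "^[\\p{L}']+"))
  !is.na(first) & first %in% .interrogative_starters
}

#' Normalise headings
#'
#' Under the package's heading convention (a line of at most eight tokens with
#' no terminal sentence punctuation that is not a list item), a
#' non-interrogative heading gets a trailing colon if it lacks punctuation,
#' and an interrogative heading (first word a WH-word or auxiliary) ends with
#' a question mark and never `?:`.
#'
#' @param text Character scalar.
#' @return Text with heading lines normalised.
#' @export
#' @examples
#' normalise_headings("Key facts")
#' normalise_headings("Can I drive after a TIA")
normalise_headings <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text)) return(text)
  lines <- stringr::str_split_1(text, "\n")
  head <- is_heading_line(lines)
  ask <- head & is_interrogative(lines)
  plain <- head & !ask
  lines[ask] <- paste0(
    stringr::str_remove(stringr::str_remove(lines[ask], "[ \t]+$"), ":+$"), "?"
  )
  add_colon <- plain & !stringr::str_detect(lines, ":$")
  lines[add_colon] <- paste0(
    stringr::str_remove(lines[add_colon], "[ \t]+$"), ":"
  )
  paste(lines, collapse = "\n")
}

#' Flatten a table into label-value sentences
#'
#' Converts an ordered set of header-cell pairs into short complete sentences
#' of the punctuation-only pattern `"Label: value."`, concatenated in input
#' order with no connectives, so tabulated material parses like prose.
#'
#' @param rows A data frame (or tibble) with columns `label` and `value`, or a
#'   list of length-2 character vectors.
#' @return A single character string; empty input gives `""`.
#' @export
#' @examples
#' flatten_table(data.frame(
#'   label = c("Vehicle", "Minimum time off driving"),
#'   value = c("Car or motorcycle", "1 month")
#' ))
flatten_table <- function(rows) {
  if (is.data.frame(rows)) {
    stopifnot(all(c("label", "value") %in% names(rows)))
    labels <- as.character(rows$label)
    values <- as.character(rows$value)
  } else {
    stopifnot(is.list(rows))
    labels <- vapply(rows, function(p) as.character(p[[1]]), character(1))
    values <- vapply(rows, function(p) as.character(p[[2]]), character(1))
  }
  if (length(labels) == 0L) return("")
  if (any(!nzchar(stringr::str_trim(labels))) ||
      any(!nzchar(stringr::str_trim(values)))) {
    pil_abort("flatten_table: every pair needs a non-empty label and value",
              "pil_invalid_input")
  }
  paste0(labels, ": ", values, ".", collapse = " ")
}

#' Normalise whitespace and line-break hyphenation
#'
#' Collapses runs of spaces/tabs to a single space, collapses two or more
#' consecutive blank lines to one, trims trailing spaces, and rejoins words
#' split across a line break by a trailing hyphen (the hyphen is removed; only
#' letter-to-letter joins are made, so intra-line hyphens like "well-known"
#' are untouched).
#'
#' @param text Character scalar.
#' @return Normalised text.
#' @export
#' @examples
#' normalise_whitespace_and_hyphenation("driv-\ning licence")
#' normalise_whitespace_and_hyphenation("a  b\t c")
normalise_whitespace_and_hyphenation <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text)) return(text)
  # rejoin line-break hyphenation: letter "-" newline letter
  text <- stringr::str_replace_all(
    text, "(\\p{L})-[ \t]*\n[ \t]*(\\p{L})", "\\1\\2"
  )
  text <- stringr::str_replace_all(text, "[ \t]+", " ")
  lines <- stringr::str_split_1(text, "\n")
  lines <- stringr::str_remove(lines, " +$")
  text <- paste(lines, collapse = "\n")
  text <- stringr::str_replace_all(text, "\n{3,}", "\n\n")
  stringr::str_remove_all(text, "^\n+|\n+$")
}

#' Standardise one leaflet
#'
#' Composes the four structural passes in fixed order (strip citations and
#' symbols, normalise bullets, normalise headings, normalise whitespace and
#' hyphenation) and reports the whitespace-token word count of the result. The
#' operation is idempotent and makes no lexical edits: surviving alphabetic
#' tokens appear in the input in the same order.
#'
#' @param leaflet_id Short character label, unique within a corpus.
#' @param body Raw leaflet text (character scalar, UTF-8).
#' @return A one-row tibble with columns `leaflet_id`, `body` (standardised
#'   text) and `word_count`.
#' @seealso [standardise_corpus()] for a whole corpus,
#'   [standardised_violations()] for the output-format checker.
#' @export
standardise_leaflet <- function(leaflet_id, body) {
  stopifnot(is.character(leaflet_id), length(leaflet_id) == 1L,
            is.character(body), length(body) == 1L)
  if (!nzchar(stringr::str_trim(body))) {
    pil_abort(sprintf("leaflet '%s': empty body, unusable leaflet", leaflet_id),
              "pil_empty_leaflet")
  }
  out <- body
  out <- strip_citations_and_symbols(out)
  out <- normalise_bullets(out)
  out <- normalise_headings(out)
  out <- normalise_whitespace_and_hyphenation(out)
  tibble::tibble(
    leaflet_id = leaflet_id,
    body = out,
    word_count = stringr::str_count(out, "\\S+")
  )
}

#' Standardise a corpus of leaflets
#'
#' @param corpus Tibble/data frame with columns `leaflet_id` and `body`.
#' @return Tibble with columns `leaflet_id`, `body`, `word_count`, one row per
#'   leaflet, input order preserved.
#' @export
standardise_corpus <- function(corpus) {
  stopifnot(all(c("leaflet_id", "body") %in% names(corpus)))
  if (anyDuplicated(corpus$leaflet_id)) {
    pil_abort("duplicate leaflet_id in corpus", "pil_invalid_input")
  }
  purrr::map2_dfr(corpus$leaflet_id, corpus$body, standardise_leaflet)
}

#' Count rule applications of the standardiser
#'
#' Diagnostic companion to [standardise_leaflet()]: how many inline citations
#' were removed, list lines normalised, headings colonised or
#' question-marked, and hyphen line-breaks rejoined.
#'
#' @param body Raw leaflet text.
#' @return Named list of non-negative integer counts.
#' @export
standardise_report <- function(body) {
  stopifnot(is.character(body), length(body) == 1L)
  citations <- stringr::str_count(body, .citation_rx)
  stripped <- strip_citations_and_symbols(body)
  lines <- stringr::str_split_1(stripped, "\n")
  bullets <- sum(stringr::str_detect(lines, .bullet_rx))
  after_bullets <- normalise_bullets(stripped)
  lines2 <- stringr::str_split_1(after_bullets, "\n")
  head <- is_heading_line(lines2)
  ask <- head & is_interrogative(lines2)
  headings_colon <- sum(head & !ask & !stringr::str_detect(lines2, ":$"))
  headings_question <- sum(ask & !stringr::str_detect(lines2, "\\?$"))
  hyphens <- stringr::str_count(after_bullets,
                                "(\\p{L})-[ \t]*\n[ \t]*(\\p{L})")
  list(
    citations_removed = citations,
    bullet_lines = bullets,
    headings_colonised = headings_colon,
    headings_questioned = headings_question,
    hyphenation_rejoined = hyphens
  )
}

#' Check standardised-text format invariants
#'
#' Line-by-line conformance checker for standardiser output: no list markers
#' at line starts, no characters outside the allow-list, every non-heading
#' line ends in terminal sentence punctuation, headings end in `:` or `?`, no
#' run of more than one space, and no more than one blank line in a row.
#'
#' @param body Standardised text.
#' @return Character vector of violation messages; `character(0)` when the
#'   text conforms.
#' @export
standardised_violations <- function(body) {
  stopifnot(is.character(body), length(body) == 1L)
  bad <- character(0)
  lines <- stringr::str_split_1(body, "\n")
  if (any(stringr::str_detect(lines, .bullet_rx))) {
    bad <- c(bad, "list marker at line start")
  }
  if (stringr::str_detect(body, .allowlist_rx)) {
    bad <- c(bad, "character outside allow-list")
  }
  if (stringr::str_detect(body, "  ")) bad <- c(bad, "run of >1 space")
  if (stringr::str_detect(body, "\n{3,}")) bad <- c(bad, ">1 blank line")
  content <- lines[nzchar(stringr::str_trim(lines))]
  ends_ok <- stringr::str_detect(content, "[.!?:]$")
  if (any(!ends_ok)) {
    bad <- c(bad, sprintf("line without terminal punctuation: '%s'",
                          content[!ends_ok][1]))
  }
  bad
}
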