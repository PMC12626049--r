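# Independent readability oracle, deliberately coded apart from the package:
# its own sentence splitting, word extraction and a plain vowel-group
# syllable counter (no -es/-ed or hiatus refinements). Agreement between the
# two routes is asserted within a tolerance that covers the heuristics'
# divergence.

oracle_syllables <- function(word) {
  w <- tolower(gsub("[^a-z]", "", tolower(word)))
  if (!nzchar(w)) return(NA_integer_)
  groups <- gregexpr("[aeiouy]+", w)[[1]]
  n <- if (groups[1] == -1L) 0L else length(groups)
  silent <- (grepl("e$", w) && !grepl("[^aeiouy]le$", w)) ||
    (grepl("[^aeiouy]es$", w) && !grepl("([sxzcg]|ch|sh)es$", w)) ||
    (grepl("[^aeiouy]ed$", w) && !grepl("[td]ed$", w))
  if (silent && n > 1L) n <- n - 1L
  max(n, 1L)
}

oracle_stats <- function(text) {
  segs <- strsplit(text, "[.!?]+")[[1]]
  segs <- segs[grepl("[A-Za-z]", segs)]
  words <- unlist(strsplit(segs, "[^A-Za-z0-9'-]+"))
  words <- words[grepl("[A-Za-z]", words)]
  syl <- vapply(words, oracle_syllables, integer(1))
  list(
    sentences = length(segs),
    words = length(words),
    syllables = sum(syl),
    characters = sum(nchar(gsub("[^A-Za-z0-9]", "", words))),
    complex = sum(syl >= 3L)
  )
}

oracle_indices <- function(text) {
  s <- oracle_stats(text)
  asl <- s$words / s$sentences
  asw <- s$syllables / s$words
  list(
    fre = 206.835 - 1.015 * asl - 84.6 * asw,
    fkg = 0.39 * asl + 11.8 * asw - 15.59,
    ari = 4.71 * s$characters / s$words + 0.5 * asl - 21.43,
    gfi = 0.4 * (asl + 100 * s$complex / s$words)
  )
}

# merge consecutive sentence pairs of a one-sentence-per-line text: the word
# and syllable streams are unchanged, the sentence count roughly halves —
# a paired text that isolates the words-per-sentence term of each index
merge_sentence_pairs <- function(body) {
  lines <- strsplit(body, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  out <- character(0)
  i <- 1L
  while (i <= length(lines)) {
    if (i < length(lines)) {
      out <- c(out, paste(sub("\\.$", "", lines[i]), lines[i + 1L]))
      i <- i + 2L
    } else {
      out <- c(out, lines[i])
      i <- i + 1L
    }
  }
  paste(out, collapse = "\n")
}

# brute-force Kendall tau over all pairs (tie-free rankings)
oracle_kendall_tau <- function(a, b) {
  n <- length(a)
  conc <- 0L
  disc <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    s <- sign(a[i] - a[j]) * sign(b[i] - b[j])
    if (s > 0) conc <- conc + 1L else if (s < 0) disc <- disc + 1L
  }
  (conc - disc) / (n * (n - 1) / 2)
}

# alphabetic token sequence, lowercased; line-break hyphens pre-joined so the
# standardiser's rejoining rule does not split the comparison baseline
lexical_tokens <- function(text) {
  text <- gsub("(\\p{L})-[ \t]*\n[ \t]*(\\p{L})", "\\1\\2", text, perl = TRUE)
  toks <- unlist(strsplit(text, "[^\\p{L}]+", perl = TRUE))
  tolower(toks[nzchar(toks)])
}

is_subsequence <- function(short, long) {
  if (length(short) == 0L) return(TRUE)
  j <- 1L
  for (x in long) {
    if (identical(x, short[j])) {
      j <- j + 1L
      if (j > length(short)) return(TRUE)
    }
  }
  FALSE
}
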