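# Shared expected values for the packaged 8-leaflet reference table.

published_composites <- c(
  "Stroke Association" = 72.8,
  "DeepSeek v3.1" = 68.3,
  "Microsoft Copilot" = 66.4,
  "ChatGPT-5 (Thinking)" = 66.3,
  "Gemini 2.5 Flash" = 59.1,
  "ChatGPT-5o (Standard)" = 51.7,
  "Claude Sonnet 4" = 44.8,
  "Perplexity AI (free)" = 29.8
)

ai_leaflet_ids <- setdiff(names(published_composites), "Stroke Association")

stats_of <- function(n_sentences, n_words, n_syllables = n_words,
                     n_characters = n_words * 4, n_complex_words = 0) {
  structure(list(n_sentences = n_sentences, n_words = n_words,
                 n_syllables = n_syllables, n_characters = n_characters,
                 n_complex_words = n_complex_words),
            class = "text_statistics")
}
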