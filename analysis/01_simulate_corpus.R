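#!/usr/bin/env Rscript
# Step 1 — simulate a leaflet-like corpus and a random instrument score table.
#
# The synthetic corpus has the structural features the standardiser targets
# (bullets, headings, citations, a flattened table, hyphenation artefacts);
# the score table samples uniformly within each instrument's scale bounds.
# Outputs: results/synthetic/corpus/*.txt, results/synthetic/scores.csv

suppressPackageStartupMessages(library(pilappraise))

out_dir <- "results/synthetic"
dir.create(file.path(out_dir, "corpus"), recursive = TRUE,
           showWarnings = FALSE)

recipe <- corpus_recipe(n_leaflets = 8, mean_sentence_length = 14,
                        syllable_ratio = 1.5, bullet_fraction = 0.3,
                        heading_every_k_sentences = 5, include_table = TRUE,
                        sentences_per_leaflet = 60, seed = 20260921L)
corpus <- generate_leaflet_text(recipe)
for (i in seq_len(nrow(corpus))) {
  writeLines(corpus$body[i],
             file.path(out_dir, "corpus",
                       paste0(corpus$leaflet_id[i], ".txt")),
             useBytes = TRUE)
}

scores <- generate_score_table(score_table_recipe(n_leaflets = 8,
                                                  seed = 20260921L))
scores$leaflet_id <- corpus$leaflet_id
write_score_table(scores, file.path(out_dir, "scores.csv"))

cat(sprintf("Simulated %d leaflets (~%d sentences each) into %s\n",
            nrow(corpus), recipe$sentences_per_leaflet, out_dir))
cat("Instrument score ranges drawn: DISCERN",
    paste(range(scores$discern), collapse = "-"),
    "| misinformation", paste(range(scores$misinfo_total), collapse = "-"),
    "\n")
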