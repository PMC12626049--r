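#!/usr/bin/env Rscript
# Step 3 — composite scoring and ranking of the packaged reference corpus.
#
# Runs the pipeline in scores-only mode on the packaged 8-leaflet raw score
# table: hybrid min-max normalisation (readability on observed corpus
# extremes, instruments on scale bounds), pre-declared weights summing to
# 9.5, composite percentage and rank. Also reports corpus and AI-subgroup
# readability medians.
# Outputs: results/composite_ranking.csv, results/ranking_report.md,
#          results/ranking.svg (if SVG device available)

suppressPackageStartupMessages(library(pilappraise))

dir.create("results", showWarnings = FALSE)
report <- run_pipeline(load_paper_fixture("table2"))
res <- report$results

readr::write_csv(res, "results/composite_ranking.csv")
report_markdown(report, "results/ranking_report.md")

cat("Composite ranking (scores-only mode):\n")
print(as.data.frame(res[, c("rank", "leaflet_id", "composite_pct")]))

ai <- setdiff(res$leaflet_id, "Stroke Association")
cat(sprintf("Corpus median FKG: %.1f\n",
            subgroup_median(report, res$leaflet_id, "fkg", digits = 1)))
cat(sprintf("AI-subgroup medians: FKG %.2f, FRE %.1f, ARI %.2f, GFI %.1f\n",
            subgroup_median(report, ai, "fkg"),
            subgroup_median(report, ai, "fre"),
            subgroup_median(report, ai, "ari"),
            subgroup_median(report, ai, "gfi")))
gap <- res$composite_pct[res$leaflet_id == "Stroke Association"] -
  res$composite_pct[res$leaflet_id == "DeepSeek v3.1"]
cat(sprintf("Benchmark-minus-runner-up gap: %.1f percentage points\n", gap))

if (requireNamespace("ggplot2", quietly = TRUE) &&
    capabilities("cairo")) {
  library(ggplot2)
  p <- ggplot(res, aes(x = reorder(leaflet_id, composite_pct),
                       y = composite_pct)) +
    geom_col(fill = "steelblue") +
    coord_flip() +
    labs(x = NULL, y = "Composite score (%)",
         title = "Weighted composite performance by leaflet source") +
    theme_minimal()
  svg("results/ranking.svg", width = 7, height = 4)
  print(p)
  dev.off()
  cat("Wrote results/ranking.svg\n")
}
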