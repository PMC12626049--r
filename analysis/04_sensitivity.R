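#!/usr/bin/env Rscript
# Step 4 — rank-stability sensitivity analysis across scaling methods.
#
# Recomputes the reference-corpus ranking under the hybrid default, observed
# min-max for every metric, z-score standardisation (rescaled to [0,1]) and
# average-rank percentiles, then reports pairwise Kendall tau between the
# four rankings.
# Outputs: results/sensitivity_rankings.csv, results/sensitivity_tau.csv

suppressPackageStartupMessages({
  library(pilappraise)
  library(dplyr)
  library(purrr)
})

dir.create("results", showWarnings = FALSE)
sa <- sensitivity_analysis(load_paper_fixture("table2"))

rankings <- imap_dfr(sa$rankings, function(r, method) {
  tibble::tibble(method = method, leaflet_id = r$leaflet_id,
                 composite_pct = r$composite_pct, rank = r$rank)
})
readr::write_csv(rankings, "results/sensitivity_rankings.csv")

tau <- tibble::as_tibble(sa$tau, rownames = "method")
readr::write_csv(tau, "results/sensitivity_tau.csv")

cat("Rank agreement (Kendall tau) between scaling methods:\n")
print(round(sa$tau, 3))
top <- rankings |> filter(rank == 1) |> distinct(method, leaflet_id)
cat("\nTop-ranked leaflet per method:\n")
print(as.data.frame(top))
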