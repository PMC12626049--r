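# pilappraise

Appraisal of patient information leaflets (PILs): readability, instrument
scores, and weighted composite ranking.

## What this is for

Leaflets on safety-critical topics — the motivating corpus covers driving
rules after a stroke in the UK — must be readable, reliable, actionable,
factually safe and properly referenced at the same time. `pilappraise`
implements a complete appraisal pipeline for such corpora:

1. **Structure-only text standardisation** so any leaflet parses
   consistently: bullet items become complete sentences, headings gain
   terminal punctuation (`:`, or `?` when interrogative), citations,
   reference blocks and decorative symbols are removed, tables flatten to
   `"Label: value."` sentences, whitespace and line-break hyphenation are
   repaired. No lexical edits, idempotent.
2. **Readability indices** from one explicit tokenisation pass (sentences
   `S`, words `W`, syllables `Y`, alphanumeric characters `C`, complex
   words `X`):
   - Flesch Reading Ease: `206.835 − 1.015·(W/S) − 84.6·(Y/W)`
   - Flesch-Kincaid Grade: `0.39·(W/S) + 11.8·(Y/W) − 15.59`
   - Automated Readability Index: `4.71·(C/W) + 0.5·(W/S) − 21.43`
   - Gunning Fog Index: `0.4·[(W/S) + 100·(X/W)]`
3. **Instrument score ingestion** with total validation: DISCERN (16–80),
   PEMAT-P understandability/actionability (percentages), a 0–6
   misinformation rubric (three 0–2 subdomains, lower = better),
   referencing quality (0–2). Human judgments are ingested, never
   automated.
4. **Composite scoring**: every metric is min-max normalised to `N_i` in
   [0, 1] with higher = better (FKG, ARI, GFI and misinformation
   reverse-coded), using *hybrid* bounds — observed corpus min/max for the
   readability indices, instrument scale bounds for the rest — then
   combined as `S = Σ W_i·N_i` with pre-declared weights
   (1, 1, 1, 1, 1.5, 0.75, 0.75, 2, 0.5; sum 9.5) and expressed as
   `100·S/ΣW` percent.
5. **Sensitivity analysis**: the ranking is recomputed under observed
   min-max everywhere, z-scores and percentile ranks, with pairwise
   Kendall tau quantifying rank stability.
6. **Synthetic corpus generation** (seeded, deterministic) so every stage
   is testable with no external data.

The packaged fixture `table2.csv` transcribes the published raw evaluation
table for eight driving-after-stroke leaflets (one expert-authored, seven
LLM-generated); `table4.csv` transcribes the item-level misinformation
subdomains.

## Worked example

```r
library(pilappraise)

ranking <- rank_leaflets(load_paper_fixture("table2"))
ranking[, c("rank", "leaflet_id", "composite_pct")]
#> # A tibble: 8 × 3
#>    rank leaflet_id            composite_pct
#>   <int> <chr>                         <dbl>
#> 1     1 Stroke Association             72.8
#> 2     2 DeepSeek v3.1                  68.3
#> 3     3 Microsoft Copilot              66.4
#> 4     4 ChatGPT-5 (Thinking)           66.3
#> 5     5 Gemini 2.5 Flash               59.1
#> 6     6 ChatGPT-5o (Standard)          51.7
#> 7     7 Claude Sonnet 4                44.8
#> 8     8 Perplexity AI (free)           29.8
```

The expert-authored leaflet ranks first at 72.8% — 4.5 percentage points
ahead of the best LLM leaflet — because the pre-declared weights emphasise
the safety-relevant domains (reliability, misinformation, referencing)
where it is strongest. Readability medians summarise the other side of the
trade-off:

```r
report <- run_pipeline(load_paper_fixture("table2"))
subgroup_median(report, report$results$leaflet_id, "fkg", digits = 1)
#> [1] 8.5     # whole corpus: secondary-school band
ai <- setdiff(report$results$leaflet_id, "Stroke Association")
subgroup_median(report, ai, "fre")
#> [1] 48      # AI-subgroup Flesch Reading Ease median
```

Standardisation and readability on raw text:

```r
std <- standardise_leaflet("demo",
  "Key facts\n• Do not drive for one month\nAsk your doctor [1].")
std$body
#> [1] "Key facts:\nDo not drive for one month.\nAsk your doctor."
readability_profile(std$body)
#> # A tibble: 1 × 4
#>     fkg   fre   ari   gfi
#> 1 -1.29 110.82 -1.61  1.47
```

(Three sentences — the colonised heading counts as one — eleven words,
twelve syllables: a deliberately tiny text, hence the off-scale "easier
than grade 0" values, reported unclamped.)

## Analysis workflow

The `analysis/` scripts run the full study sequence and write their tables
under `results/`:

| script | what it does |
|---|---|
| `01_simulate_corpus.R` | seeded synthetic leaflet corpus + random score table |
| `02_standardise_readability.R` | standardises the corpus, checks format conformance, profiles readability |
| `03_composite_ranking.R` | composite ranking of the packaged reference table, medians, markdown report, bar chart |
| `04_sensitivity.R` | rankings under four scalings + Kendall tau matrix |

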