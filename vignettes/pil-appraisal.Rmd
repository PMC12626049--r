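---
title: "Appraising patient information leaflets: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Appraising patient information leaflets: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pilappraise)
```

## The problem

Patient information leaflets (PILs) on safety-critical topics — here,
driving restrictions after a stroke — must be simultaneously *readable*
(accessible at a typical secondary-school reading level), *reliable*
(transparent, balanced, evidence-supported), *actionable* (clear next
steps), *factually safe* (no omissions of rules with legal or safety
consequences) and *traceable* (verifiable references). No single instrument
measures all five, so leaflet appraisal combines automated readability
indices with validated human-scored instruments and synthesises them into a
single weighted composite that lets a corpus of leaflets be ranked.

`pilappraise` implements that pipeline end to end: structure-only text
standardisation, four readability indices from explicit counts, validated
ingestion of human instrument scores, hybrid min-max normalisation with
pre-declared weights, composite ranking, and a rank-stability sensitivity
analysis. A seeded synthetic-corpus generator makes every stage testable
without any external data.

## Text standardisation

Readability software is sensitive to formatting, not just wording: an
unterminated bullet item merges with the next line into one spurious long
sentence, a heading without punctuation does the same, and extraction
artefacts (soft line-break hyphenation, decorative symbols) corrupt word
and syllable counts. The standardiser therefore applies four purely
structural passes, in a fixed order:

1. **Strip citations and symbols** — inline bracketed numeric citations
   (`[1]`, `[2,3]`, `[4-6]`), a terminal block introduced by a
   "References"/"Sources" heading, and any character outside a conservative
   allow-list (letters, digits, standard punctuation, currency signs,
   whitespace). An allow-list is used rather than an emoji block-list
   because it behaves identically across platforms and Unicode versions.
   A *leading* list marker is protected in this pass: it is meaningful
   structure owned by the next pass, while mid-line bullets are decoration
   and are removed.
2. **Normalise bullets** — leading bullet/hyphen/asterisk markers are
   removed (items become left-aligned lines) and a full stop is appended to
   any list line lacking terminal sentence punctuation, so list items parse
   as complete sentences.
3. **Normalise headings** — a non-interrogative heading gets a trailing
   colon if unpunctuated; an interrogative heading ends with a question
   mark, never `?:`.
4. **Normalise whitespace and hyphenation** — runs of spaces/tabs collapse
   to one space, two or more blank lines collapse to one, and a word split
   across a line break by a trailing hyphen is rejoined.

No pass paraphrases or edits words: every surviving alphabetic token of the
output appears in the input, in order (the test suite checks this as a
token-subsequence property, with line-break hyphens pre-joined in the
baseline since rejoining deliberately merges two tokens into one). The
composition is idempotent.

Two conventions had to be fixed where common practice is silent:

* **What is a heading?** A line of at most eight whitespace tokens, without
  terminal sentence punctuation, that is not a list item and does not end
  in a hyphen. The token cap separates headings from prose fragments; the
  hyphen guard prevents a line broken mid-word from being colonised before
  the whitespace pass can rejoin it (the passes run in a fixed order, so
  the heading pass sees hyphenation artefacts first). *Interrogative* means
  the first word is a WH-word or auxiliary (what/when/where/who/why/how/
  can/do/is/are/will/should/...).
* **Pass order.** Strip → bullets → headings → whitespace. Bullets must
  precede headings (an unterminated bullet item would otherwise look like a
  heading); stripping precedes both so that citation markers never count as
  line tokens.

Tabulated material is handled by `flatten_table()`, which renders ordered
label-value pairs as short complete sentences (`"Label: value."`) with no
connectives, so tables contribute honest sentence-level statistics instead
of being skipped or mangled.

## Readability indices

All four indices are computed from one tokenisation pass
(`tokenise()`), which produces sentence, word, syllable, character and
complex-word counts:

* **FRE** (Flesch Reading Ease) $= 206.835 - 1.015\,\frac{W}{S} -
  84.6\,\frac{Y}{W}$
* **FKG** (Flesch-Kincaid Grade) $= 0.39\,\frac{W}{S} +
  11.8\,\frac{Y}{W} - 15.59$
* **ARI** (Automated Readability Index) $= 4.71\,\frac{C}{W} +
  0.5\,\frac{W}{S} - 21.43$
* **GFI** (Gunning Fog Index) $= 0.4\left[\frac{W}{S} +
  100\,\frac{X}{W}\right]$

with $S$ sentences, $W$ words, $Y$ syllables, $C$ alphanumeric characters
of words, $X$ complex words. Conventions:

* **Sentences** end at `.`, `!` or `?`; a heading line ending `:` counts as
  one sentence, consistent with the standardisation goal that every line
  parse as a complete unit.
* **Words** are whitespace tokens stripped of surrounding punctuation and
  dropped if they contain no letter (so bare numbers and stray symbols do
  not count). Characters are alphanumeric only — the most common ARI
  operationalisation.
* **Syllables** come from a deterministic, dictionary-free heuristic:
  maximal vowel groups (`a e i o u y`), minus a silent terminal "e" (kept
  in consonant-"le" endings), with terminal "-es"/"-ed" silent unless the
  preceding consonant requires the vowel (sibilant + "es", t/d + "ed"),
  plus a split for the "ia" hiatus (as in *association*, *trial*) except
  inside fused word-final endings like *-cial*/*-tial*. The hiatus rule is
  the one refinement beyond the textbook counter; without it
  dictionary-syllabified anchor words such as *association* (5 syllables)
  are undercounted. The count is floored at one.
* **Complex words** (GFI) have three or more heuristic syllables, excluding
  words capitalised mid-sentence (a layout-free proxy for proper nouns) and
  words that reach three syllables only through an "-es"/"-ed" inflection —
  the classic Gunning exclusions stated operationally. Hyphenated compounds
  are split and each part assessed on its own.

Scores are reported unclamped and rounded to two decimals: an FRE outside
[0, 100] is a signal of degenerate text, not something to hide. The test
suite checks each formula against closed-form plug-ins, checks monotonicity
on paired texts that share their word and syllable streams but differ in
sentence segmentation, and checks both routes to every index against an
independently coded oracle (its own splitting and a plain vowel-group
counter) within ±0.6 grade / ±3 FRE points — a band that covers the
residual divergence between any two reasonable syllable heuristics.

Exact numerical reproduction of *published* per-leaflet readability values
is deliberately not a goal: those depend on the tokenisation of the
third-party tool used to produce them, which is unpublished. The published
raw values are instead carried as data (below).

## Instrument scores

Reliability (DISCERN, integer 16–80), understandability and actionability
(PEMAT-P, each a percentage), misinformation (three subdomains —
inappropriate content, missing content, potential harm — each 0–2, total
0–6, lower = better) and referencing quality (0–2) are *human judgments by
design*; the package ingests and validates them, it never scores text
automatically. The rubric's qualitative anchors are carried as
documentation (`misinformation_rubric()`), not enforced computationally.
PEMAT values are stored as percentages, not item counts, matching the
granularity at which such scores are published.

Score tables use a fixed, versioned CSV schema
(`leaflet_id,word_count,fkg,fre,ari,gfi,discern,pemat_u,pemat_a,misinfo_total,references`);
unknown extra columns are rejected so that packaged fixtures parse
bit-exactly. Validation is total: any malformed input produces a structured
error naming the row, column and bound — never a partially validated table.

## Normalisation, weights and the composite

Every metric is mapped to $N_i \in [0,1]$ with higher always better:
benefit metrics as $(x - \mathrm{lo})/(\mathrm{hi} - \mathrm{lo})$, cost
metrics (FKG, ARI, GFI, misinformation) reverse-coded as
$(\mathrm{hi} - x)/(\mathrm{hi} - \mathrm{lo})$. The composite is

$$S = \sum_i W_i N_i, \qquad \text{composite \%} = 100\,S \Big/ \sum_i W_i$$

with pre-declared weights FKG 1.0, FRE 1.0, ARI 1.0, GFI 1.0, DISCERN 1.5,
PEMAT-U 0.75, PEMAT-A 0.75, misinformation 2.0, references 0.5 (sum 9.5).
Composites are reported half-up at one decimal, the precision at which they
are conventionally quoted; ranking uses the unrounded value, descending,
with ties sharing the smaller rank and ordered by leaflet id.

The central open design question is **where the min-max bounds come from**.
The package default is *hybrid*:

| metric | direction | bounds |
|---|---|---|
| FKG, FRE, ARI, GFI | cost / benefit | observed corpus min/max |
| DISCERN | benefit | scale (16, 80) |
| PEMAT-U, PEMAT-A | benefit | scale (0, 100) |
| misinformation | cost | scale (0, 6) |
| references | benefit | scale (0, 2) |

The grade-level indices have no published finite scale, so corpus-relative
bounds are the only option there; bounded instruments keep their scale
bounds so that a leaflet is credited for absolute instrument performance,
not merely for beating the corpus. This hybrid is validated by an
enumeration test: among all scale-vs-observed assignments over the domains
that have a published scale, the shipped default is the only combination —
up to alternatives that are numerically identical on the packaged corpus —
whose composites reproduce the packaged reference values at one decimal.
(The references column is the numerically identical alternative: its
observed extremes, 0 and 2, coincide with its scale bounds in this corpus,
so the two choices cannot be distinguished here. The default stays "scale"
and is configurable.)

Numerical edge cases: a metric with zero observed range maps every leaflet
to 0.5 with a loud warning (keeping batch runs on degenerate synthetic
corpora alive), a value outside declared scale bounds is an error, and
corpus-relative normalisation requires at least two leaflets.

Properties the tests enforce: composite ∈ [0, 100], equal to 100 iff every
$N_i = 1$; invariance under rescaling all weights by a positive constant;
invariance of observed-bounds rankings under positive affine transforms of
a raw column; and monotonicity — improving one raw metric of one leaflet
never lowers its composite.

## Sensitivity analysis

Because min-max normalisation on a small corpus is sensitive to extremes,
`sensitivity_analysis()` recomputes the ranking under alternative scalings
— observed min-max for *all* metrics, z-scores (cost metrics negated,
columns standardised, then rescaled to [0, 1] so the weighted sum remains
a bounded percentage), and average-rank percentiles mapped to [0, 1] — and
reports pairwise Kendall tau between the rankings. On the packaged corpus
all methods agree on the top-ranked leaflet and tau stays at or above
0.79, which is the quantitative sense in which the headline ranking is
scale-robust.

## The synthetic corpus generator

The generator emulates the *structure* of standardisable leaflets, not
their prose: sentences are draws from a built-in vocabulary stratified by
syllable count (one-, two- and three-syllable word pools), which makes a
target syllables-per-word ratio constructible without a dictionary. A
recipe controls corpus size, mean sentence length (words are drawn per
sentence from a Poisson with that mean, floored at three), syllable ratio
(via the stratum mixture), bullet fraction, heading cadence (alternating
plain and interrogative headings), an optional flattened label-value table,
and the seed; inline citations, emojis, doubled spaces, extra blank lines,
a terminal references block and line-break hyphenation artefacts are
injected at fixed small rates so every standardiser rule fires on a
full-featured recipe. Generation is deterministic given the recipe.

Two measurement caveats, both deliberate: the length and syllable targets
refer to prose and bullet sentences, so the target-tracking test (realised
statistics within 10% of the recipe for ≥50 sentences) generates with
headings effectively off — headings are short colon-terminated lines that
count as sentences and would dilute the realised mean; and score tables
are sampled *uniformly* within instrument bounds, with no attempt to mimic
the correlation structure of real instrument scores.

What passing on synthetic corpora does **not** show: performance on real
leaflet prose (real vocabulary, real syllable distributions, inflected
forms, proper nouns, layout-dependent PEMAT items), agreement with any
specific third-party readability tool beyond the stated tolerance, or the
behaviour of human raters. The packaged reference table is the one bridge
to real data: the composite stage reproduces its published composites
exactly, but the readability engine's own outputs on the underlying texts
are not asserted against the published per-leaflet index values, whose
tokeniser is unknown.

## Problem sizes used by the checks

The shipped verification uses corpora deliberately sized for tight,
deterministic checks: 100 leaflets of ~15 sentences for the standardiser
property suite, 100 merged-pair texts of 12 sentences for monotonicity, 100
leaflets of 20 sentences for oracle agreement, 64 enumerated bounds
assignments on the 8-leaflet reference table, and 1,000 random 8-leaflet
score tables for the affine-invariance and weight-homogeneity sweeps.

## Worked example

```{r example}
ranking <- rank_leaflets(load_paper_fixture("table2"))
ranking[, c("rank", "leaflet_id", "composite_pct")]

report <- run_pipeline(load_paper_fixture("table2"))
subgroup_median(report, report$results$leaflet_id, "fkg", digits = 1)
```

## Known limitations

* The syllable heuristic is English-specific and, like every dictionary-free
  counter, wrong on some words; all index tolerances are stated with that in
  mind.
* The heading convention is a convention: text whose paragraphs are wrapped
  mid-sentence across short lines (rather than one sentence or paragraph
  per line) can have fragments treated as headings. Standardisation is
  designed for extracted leaflet text, where lines are semantic units.
* Human-scored instruments are ingested as ground truth; inter-rater
  reconciliation is out of scope.
* With eight leaflets, corpus-relative bounds make composites sensitive to
  single extreme values — the sensitivity analysis exists precisely to
  quantify how much the ranking depends on that choice.
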