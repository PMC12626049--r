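# End-to-end appraisal pipeline and report.
#
# Two modes share one code path:
#   * full-text mode: standardise leaflet texts, compute readability from
#     them, merge with the human-assigned instrument scores;
#   * scores-only mode: take the readability columns from the score table
#     itself (the published raw table is the canonical regression input —
#     the study corpus lives in an external archive).
# Either way the merged table is normalised, weighted, ranked and summarised.

#' Run the leaflet appraisal pipeline
#'
#' @param scores Raw score table (tibble) or path to its CSV. In full-text
#'   mode its readability columns (`word_count`, `fkg`, `fre`, `ari`, `gfi`)
#'   are recomputed from the texts; in scores-only mode (`texts = NULL`) they
#'   are used as given.
#' @param texts Optional corpus: a tibble with `leaflet_id` and `body`
#'   columns of raw leaflet text, or a directory of UTF-8 `.txt` files (file
#'   name stem = leaflet id). Ids must match the score table exactly.
#' @param scheme Weight scheme tibble; default [default_weight_scheme()].
#' @return An `appraisal_report`: list with `results` (per-leaflet raw
#'   metrics, normalised values, `weighted_sum`, `composite_pct`, `rank`,
#'   ordered by rank), `scheme`, and `medians` (per-index corpus medians,
#'   unrounded).
#' @export
run_pipeline <- function(scores, texts = NULL,
                         scheme = default_weight_scheme()) {
  if (is.character(scores)) scores <- load_score_table(scores)
  scores <- validate_score_table(scores)

  if (!is.null(texts)) {
    if (is.character(texts)) texts <- read_text_dir(texts)
    std <- standardise_corpus(texts)
    only_texts <- setdiff(std$leaflet_id, scores$leaflet_id)
    only_scores <- setdiff(scores$leaflet_id, std$leaflet_id)
    if (length(only_texts) || length(only_scores)) {
      pil_abort(sprintf(
        "leaflet ids do not match: only in texts {%s}; only in scores {%s}",
        paste(only_texts, collapse = ", "),
        paste(only_scores, collapse = ", ")), "pil_id_mismatch")
    }
    prof <- purrr::map_dfr(seq_len(nrow(std)), function(i) {
      p <- readability_profile(std$body[i])
      tibble::tibble(leaflet_id = std$leaflet_id[i],
                     word_count = std$word_count[i], p)
    })
    scores <- dplyr::select(scores, -"word_count", -"fkg", -"fre", -"ari",
                            -"gfi")
    scores <- dplyr::inner_join(prof, scores, by = "leaflet_id")
    scores <- validate_score_table(scores)
  }

  results <- rank_leaflets(scores, scheme)
  raw_cols <- setdiff(names(scores), "leaflet_id")
  results <- dplyr::left_join(
    results,
    dplyr::rename_with(scores, ~ paste0("raw_", .x), dplyr::all_of(raw_cols)),
    by = "leaflet_id"
  )
  medians <- vapply(c("fkg", "fre", "ari", "gfi"),
                    function(m) stats::median(scores[[m]]), numeric(1))
  structure(list(results = results, scheme = scheme, medians = medians),
            class = "appraisal_report")
}

read_text_dir <- function(dir) {
  if (!dir.exists(dir)) {
    pil_abort(sprintf("text directory not found: %s", dir),
              "pil_invalid_input")
  }
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  if (length(files) == 0L) {
    pil_abort(sprintf("no .txt leaflets in %s", dir), "pil_invalid_input")
  }
  tibble::tibble(
    leaflet_id = tools::file_path_sans_ext(basename(files)),
    body = vapply(files, function(f) {
      paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = "\n")
    }, character(1))
  )
}

#' @export
print.appraisal_report <- function(x, ...) {
  cat("Leaflet appraisal report\n")
  print(dplyr::select(x$results, "rank", "leaflet_id", "composite_pct"))
  invisible(x)
}

#' Median of a readability index over a subgroup
#'
#' Median with mean-of-middle-two for even-sized subsets. Unrounded by
#' default; pass `digits` to report at a chosen precision (half-up), e.g. one
#' decimal to match how corpus medians are usually quoted.
#'
#' @param report An `appraisal_report`.
#' @param ids Character vector of leaflet ids (non-empty, all present).
#' @param index One of `"fkg"`, `"fre"`, `"ari"`, `"gfi"`.
#' @param digits Optional decimal places for reporting (default: unrounded).
#' @return The median value.
#' @export
subgroup_median <- function(report, ids, index = c("fkg", "fre", "ari", "gfi"),
                            digits = NULL) {
  stopifnot(inherits(report, "appraisal_report"), length(ids) >= 1)
  index <- match.arg(index)
  res <- report$results
  unknown <- setdiff(ids, res$leaflet_id)
  if (length(unknown)) {
    pil_abort(sprintf("unknown leaflet id(s): %s",
                      paste(unknown, collapse = ", ")), "pil_invalid_input")
  }
  x <- res[[paste0("raw_", index)]][match(ids, res$leaflet_id)]
  m <- stats::median(x)
  if (is.null(digits)) m else round_half_up(m, digits)
}

#' Render an appraisal report as markdown
#'
#' A compact ranking table (rank, source, composite percentage) followed by
#' the per-index corpus medians. Byte-for-byte deterministic given identical
#' inputs.
#'
#' @param report An `appraisal_report`.
#' @param path Optional file to write to.
#' @return The markdown text (character scalar), invisibly if written.
#' @export
report_markdown <- function(report, path = NULL) {
  stopifnot(inherits(report, "appraisal_report"))
  res <- report$results
  lines <- c(
    "# Leaflet appraisal",
    "",
    "| Rank | Source | Composite score (%) |",
    "|-----:|:-------|--------------------:|",
    sprintf("| %d | %s | %.1f |", res$rank, res$leaflet_id,
            res$composite_pct),
    "",
    "Corpus medians: " %+%
      paste(sprintf("%s %.2f", toupper(names(report$medians)),
                    report$medians), collapse = ", ") %+% "."
  )
  text <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(text, path, useBytes = TRUE)
    return(invisible(text))
  }
  text
}

`%+%` <- function(a, b) paste0(a, b)
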