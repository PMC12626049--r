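# Hybrid min-max normalization, pre-declared weights, composite ranking.
#
# Every raw metric is mapped to N in [0, 1] with higher always better:
# benefit metrics as (x - lo)/(hi - lo), cost metrics (FKG, ARI, GFI,
# misinformation) reverse-coded as (hi - x)/(hi - lo). The bounds are hybrid:
# readability indices, which have no published scale, use the observed corpus
# min/max; bounded instruments use their scale limits — DISCERN (16, 80),
# PEMAT-U/A (0, 100), misinformation (0, 6), references (0, 2). The composite
# is S = sum(W_i * N_i) with pre-declared weights, expressed as a percentage
# of the maximum attainable weighted sum, 100 * S / sum(W).

#' Default metric specifications and weights
#'
#' The pre-declared weighting scheme over the nine metrics: FKG 1.0, FRE 1.0,
#' ARI 1.0, GFI 1.0, DISCERN 1.5, PEMAT-U 0.75, PEMAT-A 0.75, misinformation
#' 2.0, references 0.5 (sum 9.5). Direction and bounds source per metric as
#' described in the package vignette: readability on observed corpus min/max,
#' instruments on their scale bounds.
#'
#' @return A tibble with columns `name`, `direction` ("benefit"/"cost"),
#'   `bounds_source` ("scale"/"observed"), `scale_min`, `scale_max`, `weight`.
#' @export
default_weight_scheme <- function() {
  tibble::tribble(
    ~name,            ~direction, ~bounds_source, ~scale_min, ~scale_max, ~weight,
    "fkg",            "cost",     "observed",     NA_real_,   NA_real_,   1.0,
    "fre",            "benefit",  "observed",     NA_real_,   NA_real_,   1.0,
    "ari",            "cost",     "observed",     NA_real_,   NA_real_,   1.0,
    "gfi",            "cost",     "observed",     NA_real_,   NA_real_,   1.0,
    "discern",        "benefit",  "scale",        16,         80,         1.5,
    "pemat_u",        "benefit",  "scale",        0,          100,        0.75,
    "pemat_a",        "benefit",  "scale",        0,          100,        0.75,
    "misinfo_total",  "cost",     "scale",        0,          6,          2.0,
    "references",     "benefit",  "scale",        0,          2,          0.5
  )
}

check_scheme <- function(scheme) {
  need <- c("name", "direction", "bounds_source", "scale_min", "scale_max",
            "weight")
  stopifnot(all(need %in% names(scheme)))
  stopifnot(all(scheme$direction %in% c("benefit", "cost")),
            all(scheme$bounds_source %in% c("scale", "observed")),
            all(scheme$weight >= 0))
  sc <- scheme$bounds_source == "scale"
  if (any(sc & !(scheme$scale_min < scheme$scale_max))) {
    pil_abort("scale bounds need scale_min < scale_max", "pil_invalid_input")
  }
  scheme
}

#' Min-max normalise one metric column
#'
#' Maps raw values to \[0, 1\] with higher = better. Benefit metrics use
#' `(x - lo)/(hi - lo)`; cost metrics are reverse-coded as
#' `(hi - x)/(hi - lo)`. `lo`/`hi` are the metric's scale bounds
#' (`bounds_source = "scale"`) or the observed min/max of `values`
#' (`"observed"`, requiring >= 2 values). A degenerate observed range maps
#' every value to 0.5 with a warning; a value outside declared scale bounds is
#' an error.
#'
#' @param values Numeric vector of raw per-leaflet values.
#' @param spec One row of a weight scheme (list or one-row data frame) with
#'   `name`, `direction`, `bounds_source`, `scale_min`, `scale_max`.
#' @return Numeric vector of normalised values in \[0, 1\].
#' @export
#' @examples
#' normalise_metric(65, list(name = "discern", direction = "benefit",
#'                           bounds_source = "scale",
#'                           scale_min = 16, scale_max = 80))
normalise_metric <- function(values, spec) {
  stopifnot(is.numeric(values), all(is.finite(values)))
  if (identical(spec$bounds_source, "scale")) {
    lo <- spec$scale_min
    hi <- spec$scale_max
    if (any(values < lo | values > hi)) {
      pil_abort(sprintf("%s: value outside scale bounds [%s, %s]",
                        spec$name, lo, hi), "pil_out_of_bounds")
    }
  } else {
    if (length(values) < 2L) {
      pil_abort("observed bounds need >= 2 values", "pil_invalid_input")
    }
    lo <- min(values)
    hi <- max(values)
    if (hi == lo) {
      warning(sprintf(
        "%s: zero observed range; all normalised values set to 0.5",
        spec$name), call. = FALSE)
      return(rep(0.5, length(values)))
    }
  }
  if (identical(spec$direction, "cost")) (hi - values) / (hi - lo)
  else (values - lo) / (hi - lo)
}

#' Normalise a raw score table
#'
#' Applies [normalise_metric()] to every metric of the scheme, producing the
#' leaflets-by-metrics matrix of normalised values N_i in \[0, 1\] with higher
#' always better.
#'
#' @param table A validated raw score table (see [load_score_table()]).
#' @param scheme A weight scheme tibble; default [default_weight_scheme()].
#' @return Tibble with `leaflet_id` and one column per metric.
#' @export
normalise_table <- function(table, scheme = default_weight_scheme()) {
  scheme <- check_scheme(scheme)
  miss <- setdiff(scheme$name, names(table))
  if (length(miss)) {
    pil_abort(sprintf("missing metric column(s): %s",
                      paste(miss, collapse = ", ")), "pil_schema")
  }
  out <- tibble::tibble(leaflet_id = table$leaflet_id)
  for (i in seq_len(nrow(scheme))) {
    spec <- as.list(scheme[i, ])
    out[[spec$name]] <- normalise_metric(table[[spec$name]], spec)
  }
  out
}

#' Composite score of one normalised row
#'
#' `S = sum(W_i * N_i)` over the scheme's metrics, with the composite
#' percentage `100 * S / sum(W)` — the share of the maximum attainable
#' weighted sum.
#'
#' @param normalised_row Named list / one-row data frame of normalised values,
#'   covering every metric in the scheme.
#' @param scheme Weight scheme tibble.
#' @return List with `weighted_sum` and `composite_pct` (unrounded).
#' @export
composite_score <- function(normalised_row, scheme = default_weight_scheme()) {
  scheme <- check_scheme(scheme)
  miss <- setdiff(scheme$name, names(normalised_row))
  if (length(miss)) {
    pil_abort(sprintf("composite_score: missing metric '%s'", miss[1]),
              "pil_schema")
  }
  n <- vapply(scheme$name, function(m) as.numeric(normalised_row[[m]]),
              numeric(1))
  s <- sum(scheme$weight * n)
  list(weighted_sum = s, composite_pct = 100 * s / sum(scheme$weight))
}

#' Rank a corpus of leaflets by composite score
#'
#' Normalises, computes the weighted composite for every leaflet, and sorts
#' descending by composite percentage. Ties share the smaller (best) rank and
#' are ordered by `leaflet_id`. The reported `composite_pct` is rounded
#' half-up to one decimal, matching the precision at which composites are
#' quoted; ranking uses the unrounded value.
#'
#' @param table Raw score table (tibble) or path to its CSV.
#' @param scheme Weight scheme tibble.
#' @return Tibble ordered by rank with `leaflet_id`, the nine normalised
#'   columns, `weighted_sum`, `composite_pct`, `rank`.
#' @export
rank_leaflets <- function(table, scheme = default_weight_scheme()) {
  if (is.character(table)) table <- load_score_table(table)
  table <- validate_score_table(table)
  norm <- normalise_table(table, scheme)
  cs <- purrr::map(seq_len(nrow(norm)),
                   function(i) composite_score(norm[i, ], scheme))
  pct <- vapply(cs, `[[`, numeric(1), "composite_pct")
  out <- norm
  out$weighted_sum <- vapply(cs, `[[`, numeric(1), "weighted_sum")
  out$composite_pct <- round_half_up(pct, 1)
  ord <- order(-pct, out$leaflet_id)
  out <- out[ord, ]
  out$rank <- as.integer(rank(-pct[ord], ties.method = "min"))
  out
}

#' Rank-stability sensitivity analysis across scaling methods
#'
#' Recomputes the composite ranking under alternative normalisations and
#' measures pairwise rank agreement by Kendall's tau:
#' \describe{
#'   \item{paper_default}{the hybrid scheme exactly as supplied.}
#'   \item{observed_minmax_all}{every metric on observed corpus min/max
#'     (directions kept).}
#'   \item{zscore}{cost metrics negated, each column standardised to zero
#'     mean and unit variance, then min-max rescaled to \[0, 1\] for
#'     compositing.}
#'   \item{percentile_rank}{average-rank percentiles mapped to \[0, 1\]
#'     (cost metrics ranked on their negation).}
#' }
#'
#' @param table Raw score table or path to its CSV.
#' @param scheme Weight scheme tibble.
#' @param methods Character vector, subset of the four method names above.
#' @return List with `rankings` (named list of [rank_leaflets()]-shaped
#'   tibbles) and `tau` (pairwise Kendall tau matrix over the methods).
#' @export
sensitivity_analysis <- function(table, scheme = default_weight_scheme(),
                                 methods = c("paper_default",
                                             "observed_minmax_all",
                                             "zscore", "percentile_rank")) {
  known <- c("paper_default", "observed_minmax_all", "zscore",
             "percentile_rank")
  bad <- setdiff(methods, known)
  if (length(bad)) {
    pil_abort(sprintf("unknown scaling method '%s'", bad[1]),
              "pil_invalid_input")
  }
  if (is.character(table)) table <- load_score_table(table)
  table <- validate_score_table(table)
  scheme <- check_scheme(scheme)

  rankings <- lapply(methods, function(m) {
    switch(m,
      paper_default = rank_leaflets(table, scheme),
      observed_minmax_all = {
        sch <- scheme
        sch$bounds_source <- "observed"
        rank_leaflets(table, sch)
      },
      zscore = rank_from_normalised(rescaled_zscores(table, scheme), scheme),
      percentile_rank = rank_from_normalised(
        percentile_ranks(table, scheme), scheme)
    )
  })
  names(rankings) <- methods

  tau <- diag(1, length(methods))
  dimnames(tau) <- list(methods, methods)
  if (length(methods) > 1L) {
    for (i in seq_along(methods)) for (j in seq_along(methods)) {
      if (i < j) {
        ri <- rankings[[i]]
        rj <- rankings[[j]]
        m <- match(ri$leaflet_id, rj$leaflet_id)
        tau[i, j] <- tau[j, i] <-
          stats::cor(ri$rank, rj$rank[m], method = "kendall")
      }
    }
  }
  list(rankings = rankings, tau = tau)
}

# composite + rank from an already-normalised table
rank_from_normalised <- function(norm, scheme) {
  cs <- purrr::map(seq_len(nrow(norm)),
                   function(i) composite_score(norm[i, ], scheme))
  pct <- vapply(cs, `[[`, numeric(1), "composite_pct")
  out <- norm
  out$weighted_sum <- vapply(cs, `[[`, numeric(1), "weighted_sum")
  out$composite_pct <- round_half_up(pct, 1)
  ord <- order(-pct, out$leaflet_id)
  out <- out[ord, ]
  out$rank <- as.integer(rank(-pct[ord], ties.method = "min"))
  out
}

rescaled_zscores <- function(table, scheme) {
  out <- tibble::tibble(leaflet_id = table$leaflet_id)
  for (i in seq_len(nrow(scheme))) {
    spec <- as.list(scheme[i, ])
    x <- table[[spec$name]]
    if (identical(spec$direction, "cost")) x <- -x
    z <- if (stats::sd(x) == 0) rep(0, length(x)) else as.numeric(scale(x))
    rng <- range(z)
    out[[spec$name]] <- if (diff(rng) == 0) rep(0.5, length(z))
                        else (z - rng[1]) / diff(rng)
  }
  out
}

percentile_ranks <- function(table, scheme) {
  out <- tibble::tibble(leaflet_id = table$leaflet_id)
  n <- nrow(table)
  for (i in seq_len(nrow(scheme))) {
    spec <- as.list(scheme[i, ])
    x <- table[[spec$name]]
    if (identical(spec$direction, "cost")) x <- -x
    r <- rank(x, ties.method = "average")
    out[[spec$name]] <- if (n == 1L) rep(0.5, n) else (r - 1) / (n - 1)
  }
  out
}
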