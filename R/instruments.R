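# Data model and validation for human-assigned instrument scores.
#
# The appraisal framework ingests (never automates) human judgments on five
# domains: DISCERN reliability (16-80), PEMAT-P understandability and
# actionability (percentages), a three-subdomain misinformation rubric (each
# subdomain 0-2, total 0-6, lower = better) and referencing quality (0-2).

#' Qualitative anchors of the misinformation rubric
#'
#' The scoring anchors for the three misinformation subdomains, carried as
#' documentation rather than enforced computationally — scoring is human
#' judgment by design. Levels: 0 = none detected, 1 = minor
#' ambiguity/omission without safety implications, 2 = major omission or
#' phrasing with potential safety consequences.
#'
#' @format A tibble with columns `subdomain`, `score`, `anchor`.
#' @export
misinformation_rubric <- function() {
  tibble::tribble(
    ~subdomain, ~score, ~anchor,
    "inappropriate_content", 0L, "No misleading or unsafe phrasing",
    "inappropriate_content", 1L, "Minor ambiguous phrasing without safety impact",
    "inappropriate_content", 2L, "Clear misleading phrasing or potentially unsafe advice",
    "missing_content", 0L, "No omissions of key rules",
    "missing_content", 1L, "Minor omission that does not change safety",
    "missing_content", 2L, "Major omission of a key rule affecting safety or legal status",
    "potential_harm", 0L, "No statements likely to cause harm",
    "potential_harm", 1L, "Low likelihood of harm if misinterpreted",
    "potential_harm", 2L, "Non-trivial risk of harm or legally risky advice"
  )
}

check_range <- function(value, field, lo, hi, integer = TRUE) {
  ok <- length(value) == 1L && is.numeric(value) && is.finite(value) &&
    value >= lo && value <= hi && (!integer || value == round(value))
  if (!ok) {
    pil_abort(
      sprintf("%s must be %s in [%s, %s]; got %s", field,
              if (integer) "an integer" else "a number", lo, hi,
              paste(format(value), collapse = ", ")),
      "pil_out_of_bounds"
    )
  }
  invisible(value)
}

#' Construct an instrument score bundle for one leaflet
#'
#' @param leaflet_id Short character label.
#' @param discern DISCERN total, integer in 16-80.
#' @param pemat_u,pemat_a PEMAT-P understandability / actionability, percent
#'   in \[0, 100\].
#' @param inappropriate_content,missing_content,potential_harm Misinformation
#'   subdomain scores, each in \{0, 1, 2\}.
#' @param referencing Referencing quality, in \{0, 1, 2\}.
#' @param rationale Optional free-text rationale for the misinformation
#'   scores.
#' @return A validated `instrument_bundle` (named list).
#' @export
instrument_bundle <- function(leaflet_id, discern, pemat_u, pemat_a,
                              inappropriate_content, missing_content,
                              potential_harm, referencing, rationale = "") {
  b <- structure(
    list(
      leaflet_id = leaflet_id,
      discern = discern,
      pemat_u = pemat_u,
      pemat_a = pemat_a,
      inappropriate_content = inappropriate_content,
      missing_content = missing_content,
      potential_harm = potential_harm,
      referencing = referencing,
      rationale = rationale
    ),
    class = "instrument_bundle"
  )
  validate_bundle(b)
}

#' Validate an instrument bundle
#'
#' Returns the bundle unchanged iff every instrument invariant holds;
#' otherwise signals an error naming the violated field and its bounds.
#'
#' @param b An `instrument_bundle`.
#' @return The validated bundle, invisibly usable as before.
#' @export
validate_bundle <- function(b) {
  stopifnot(is.list(b), is.character(b$leaflet_id), nzchar(b$leaflet_id))
  check_range(b$discern, "discern", 16, 80)
  check_range(b$pemat_u, "pemat_u", 0, 100, integer = FALSE)
  check_range(b$pemat_a, "pemat_a", 0, 100, integer = FALSE)
  check_range(b$inappropriate_content, "inappropriate_content", 0, 2)
  check_range(b$missing_content, "missing_content", 0, 2)
  check_range(b$potential_harm, "potential_harm", 0, 2)
  check_range(b$referencing, "references", 0, 2)
  b
}

#' Misinformation total
#'
#' Sum of the three misinformation subdomains; range 0-6, lower = better.
#'
#' @param inappropriate_content,missing_content,potential_harm Subdomain
#'   scores in \{0, 1, 2\} (vectors allowed), or pass a single
#'   `instrument_bundle` as the first argument.
#' @return Integer total(s) in 0-6.
#' @export
#' @examples
#' misinformation_total(0, 2, 1)
misinformation_total <- function(inappropriate_content, missing_content = NULL,
                                 potential_harm = NULL) {
  if (inherits(inappropriate_content, "instrument_bundle")) {
    b <- inappropriate_content
    return(misinformation_total(b$inappropriate_content, b$missing_content,
                                b$potential_harm))
  }
  vals <- cbind(inappropriate_content, missing_content, potential_harm)
  if (any(!is.finite(vals)) || any(vals != round(vals)) ||
      any(vals < 0) || any(vals > 2)) {
    pil_abort("misinformation subdomains must each be 0, 1 or 2",
              "pil_out_of_bounds")
  }
  as.integer(rowSums(vals))
}

# fixed, versioned CSV schema (exact header order); unknown columns rejected
score_table_schema <- c(
  "leaflet_id", "word_count", "fkg", "fre", "ari", "gfi",
  "discern", "pemat_u", "pemat_a", "misinfo_total", "references"
)

validate_score_table <- function(tab, where = "score table") {
  miss <- setdiff(score_table_schema, names(tab))
  extra <- setdiff(names(tab), score_table_schema)
  if (length(miss) || length(extra)) {
    pil_abort(sprintf(
      "%s: columns must be exactly {%s}; missing {%s}, unknown {%s}",
      where, paste(score_table_schema, collapse = ","),
      paste(miss, collapse = ","), paste(extra, collapse = ",")),
      "pil_schema")
  }
  tab <- tab[, score_table_schema]
  if (nrow(tab) < 2L) {
    pil_abort(paste0(where, ": >=2 leaflets required for corpus-relative ",
                     "normalization"), "pil_invalid_input")
  }
  if (anyDuplicated(tab$leaflet_id)) {
    pil_abort(sprintf("%s: duplicate leaflet_id '%s'", where,
                      tab$leaflet_id[duplicated(tab$leaflet_id)][1]),
              "pil_invalid_input")
  }
  bounds <- list(
    word_count = c(1, Inf), discern = c(16, 80), pemat_u = c(0, 100),
    pemat_a = c(0, 100), misinfo_total = c(0, 6), references = c(0, 2)
  )
  int_cols <- c("word_count", "discern", "misinfo_total", "references")
  for (col in setdiff(score_table_schema, "leaflet_id")) {
    x <- tab[[col]]
    if (!is.numeric(x) || any(!is.finite(x))) {
      pil_abort(sprintf("%s: column '%s' must be finite numeric", where, col),
                "pil_schema")
    }
    b <- bounds[[col]]
    if (!is.null(b)) {
      off <- which(x < b[1] | x > b[2] |
                     (col %in% int_cols & x != round(x)))
      if (length(off)) {
        pil_abort(sprintf(
          "%s: row %d, column '%s': value %s outside %s-%s", where, off[1],
          col, format(x[off[1]]), b[1], b[2]), "pil_out_of_bounds")
      }
    }
  }
  tibble::as_tibble(tab)
}

#' Load a raw score table
#'
#' Reads and validates a leaflets-by-metrics CSV with the fixed schema
#' `leaflet_id,word_count,fkg,fre,ari,gfi,discern,pemat_u,pemat_a,misinfo_total,references`
#' (exact header, no extra columns). Row order is preserved. Any violation —
#' missing column, duplicate id, out-of-bounds value — is reported with its
#' row and column; a table is never returned partially validated.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble of raw scores.
#' @export
load_score_table <- function(path) {
  if (!file.exists(path)) {
    pil_abort(sprintf("score table not found: %s", path), "pil_invalid_input")
  }
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_score_table(tab, where = basename(path))
}

#' Write a raw score table
#'
#' Inverse of [load_score_table()]: validates, then writes CSV with the fixed
#' schema header. `write_score_table()` then `load_score_table()` is the
#' identity on any valid table.
#'
#' @param tab A raw score table (tibble/data frame with the schema columns).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(tab, path) {
  tab <- validate_score_table(tab)
  readr::write_csv(tab, path)
  invisible(path)
}
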