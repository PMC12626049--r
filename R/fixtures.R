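# Packaged reference fixtures: the published 8-leaflet raw score table and
# the item-level misinformation subdomain table, transcribed as CSV. A frozen
# checksum guards against accidental edits — the composite-reproduction tests
# are only meaningful against the exact published numbers.

.fixture_md5 <- c(
  table2 = "fee8a63a6921b0d3b16ec8798189ad8c",
  table4 = "25d03fc70d357051a94da106b303a895"
)

#' Load a packaged reference fixture
#'
#' `"table2"` is the published raw evaluation table for the eight
#' driving-after-stroke leaflets (word count, four readability indices,
#' DISCERN, PEMAT-U/A, misinformation total, references), returned as a
#' validated raw score table. `"table4"` is the item-level misinformation
#' assessment (three subdomains plus total per leaflet). The file's checksum
#' is verified before parsing.
#'
#' @param name `"table2"` or `"table4"`.
#' @return A tibble; for `"table2"` it passes [load_score_table()]
#'   validation, for `"table4"` it has columns `leaflet_id`,
#'   `inappropriate_content`, `missing_content`, `potential_harm`, `total`.
#' @export
#' @examples
#' load_paper_fixture("table2")
load_paper_fixture <- function(name = c("table2", "table4")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"),
                      package = "pilappraise", mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, unname(.fixture_md5[name]))) {
    pil_abort(sprintf("fixture '%s' failed its checksum (tampered file?)",
                      name), "pil_fixture_checksum")
  }
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (name == "table2") {
    validate_score_table(tab, where = "table2 fixture")
  } else {
    stopifnot(identical(names(tab), c("leaflet_id", "inappropriate_content",
                                      "missing_content", "potential_harm",
                                      "total")))
    tot <- misinformation_total(tab$inappropriate_content,
                                tab$missing_content, tab$potential_harm)
    stopifnot(all(tot == tab$total))
    tab
  }
}
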