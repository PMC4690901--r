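#' Packaged supplier roster reported by the 24 Baltimore corner stores
#'
#' Loads the transcribed supplier roster that the 24 sampled corner
#' storeowners reported: the names of suppliers in each of the seven
#' categories, listed separately for the unhealthy (UHSN) and healthy (HSN)
#' supplier networks. One chain with two distribution sites appears in the
#' HSN roster as a single identity with a multiplicity annotation of 2;
#' [roster_summary()] exposes both the multiplicity-expanded "entries" count
#' and the name-collapsed "distinct" count.
#'
#' @return Tibble with columns `network` (`"HSN"`/`"UHSN"`), `category`,
#'   `name`, `multiplicity`.
#' @export
#' @examples
#' roster <- supplier_roster_fixture()
#' hsn <- roster[roster$network == "HSN", ]
#' roster_summary(hsn, roster[roster$network == "UHSN", ])
supplier_roster_fixture <- function() {
  path <- system.file("extdata", "table2_roster.csv", package = "cornernet")
  readr::read_csv(path, col_types = readr::cols(
    network = readr::col_character(),
    category = readr::col_character(),
    name = readr::col_character(),
    multiplicity = readr::col_integer()
  ), progress = FALSE)
}

#' Write the packaged roster fixture to CSV files
#'
#' @param dir Output directory; one CSV per network mode plus the combined
#'   roster.
#' @return Invisibly, the written paths.
#' @export
write_roster_fixture <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  roster <- supplier_roster_fixture()
  paths <- file.path(dir, c("roster.csv", "roster_hsn.csv", "roster_uhsn.csv"))
  readr::write_csv(roster, paths[1], progress = FALSE)
  readr::write_csv(roster[roster$network == "HSN", ], paths[2], progress = FALSE)
  readr::write_csv(roster[roster$network == "UHSN", ], paths[3], progress = FALSE)
  invisible(paths)
}
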