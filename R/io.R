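# CSV round-trip for the six scenario tables. GEOIDs are 5-character
# zero-padded strings; readers force character so leading zeros survive.

#' Write or read the six scenario tables as CSV
#'
#' Tables are `geography`, `weather`, `soil`, `planting`, `apsim`, `yield`;
#' one `<name>.csv` per table with a header row.
#'
#' @param panels named list as returned by [simulate_scenario()].
#' @param dir directory (created if absent).
#' @return `read_scenario_csvs()` returns the named list of data.tables.
#' @export
write_scenario_csvs <- function(panels, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("geography", "weather", "soil", "planting", "apsim", "yield"))
    data.table::fwrite(panels[[nm]], file.path(dir, paste0(nm, ".csv")),
                       quote = TRUE)
  invisible(dir)
}

#' @rdname write_scenario_csvs
#' @export
read_scenario_csvs <- function(dir) {
  rd <- function(nm, classes) {
    data.table::fread(file.path(dir, paste0(nm, ".csv")),
                      colClasses = classes, data.table = TRUE)
  }
  list(geography = rd("geography", list(character = "geoid")),
       weather = rd("weather", list(character = "geoid")),
       soil = rd("soil", list(character = "geoid")),
       planting = rd("planting", list(character = "state")),
       apsim = rd("apsim", list(character = "geoid")),
       yield = rd("yield", list(character = "geoid")))
}
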