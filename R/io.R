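# Plain-text scene and table I/O. Rasters travel as long CSV grids plus a
# JSON metadata sidecar carrying the geotransform (pixel size, units) and
# nodata convention (empty CSV cells), so round-trips preserve geometry
# without a binary raster dependency.

#' Write / read a synthetic scene directory
#'
#' Lays a [simulate_frost_scene()] result out as plain-text files:
#' `reflectance.csv` (`row, col, date, red, nir`; empty cells = missing
#' observation), `crop_fraction.csv`, `history.csv` (`year_index, date,
#' ndvi`), `truth.csv`, and `scene.json` (geotransform, dates, frost onset,
#' true affected area, seed).
#'
#' @param scene A `frost_scene`.
#' @param dir Directory to create/fill.
#' @return `write_scene()` returns `dir` invisibly; `read_scene()` returns a
#'   `frost_scene`.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(scene$reflectance, file.path(dir, "reflectance.csv"))
  readr::write_csv(scene$crop, file.path(dir, "crop_fraction.csv"))
  readr::write_csv(scene$truth, file.path(dir, "truth.csv"))
  hist_tbl <- purrr::imap_dfr(scene$history, function(cv, i) {
    tibble::tibble(year_index = i, date = cv$date, ndvi = cv$ndvi)
  })
  readr::write_csv(hist_tbl, file.path(dir, "history.csv"))
  jsonlite::write_json(
    list(
      geotransform = scene$geotransform,
      start_date = format(scene$dates[1L]),
      n_days = length(scene$dates),
      met_start = format(scene$met_start),
      true_affected_area_mu = scene$true_affected_area_mu,
      seed = scene$seed,
      nodata = "empty CSV cell"
    ),
    file.path(dir, "scene.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' @rdname write_scene
#' @export
read_scene <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "scene.json"))
  refl <- readr::read_csv(file.path(dir, "reflectance.csv"),
                          show_col_types = FALSE)
  require_columns(refl, c("row", "col", "date", "red", "nir"),
                  "reflectance stack")
  crop <- readr::read_csv(file.path(dir, "crop_fraction.csv"),
                          show_col_types = FALSE)
  require_columns(crop, c("row", "col", "fraction"), "crop-fraction raster")
  truth_path <- file.path(dir, "truth.csv")
  truth <- NULL
  if (file.exists(truth_path)) {
    truth <- readr::read_csv(truth_path, show_col_types = FALSE)
  }
  hist_tbl <- readr::read_csv(file.path(dir, "history.csv"),
                              show_col_types = FALSE)
  history <- hist_tbl |>
    dplyr::group_by(.data$year_index) |>
    dplyr::group_map(~ frost_curve(.x$date, .x$ndvi))
  start <- as.Date(meta$start_date)
  dates <- start + seq_len(meta$n_days) - 1L
  structure(
    list(
      reflectance = refl,
      crop = crop,
      history = history,
      truth = truth,
      true_affected_area_mu = meta$true_affected_area_mu,
      geotransform = meta$geotransform,
      dates = dates,
      met_start = as.Date(meta$met_start),
      params = NULL,
      seed = meta$seed
    ),
    class = "frost_scene"
  )
}

#' Read a county-level yield table
#'
#' Expected CSV schema: `unit_name, year, area, production, yield` (area in
#' mu, production in tonnes, yield in mass per area). A missing `yield`
#' column is derived as `production / area`; any other missing column is a
#' schema error naming the column.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_yield_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  if (!"yield" %in% names(tbl) &&
      all(c("area", "production") %in% names(tbl))) {
    tbl$yield <- tbl$production / tbl$area
  }
  require_columns(tbl, c("unit_name", "year", "yield"), "yield table")
  tbl
}

#' Write / read a single-band grid as CSV
#'
#' Long-format single-band raster exchange: columns `row`, `col` and one
#' value column; empty cells encode nodata.
#'
#' @param grid Tibble with `row`, `col` and the value column.
#' @param path CSV path.
#' @param value Name of the value column.
#' @return `write_grid_csv()` returns `path` invisibly; `read_grid_csv()`
#'   the tibble.
#' @export
write_grid_csv <- function(grid, path, value = "value") {
  require_columns(grid, c("row", "col", value), "grid")
  readr::write_csv(grid[c("row", "col", value)], path)
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path, value = "value") {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  require_columns(tbl, c("row", "col", value), "grid CSV")
  tbl
}
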