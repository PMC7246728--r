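#' Read / write stoichiometry time-series tables
#'
#' The exchange format for SWATH-MS-shaped complex stoichiometry data: a
#' tab-separated table with columns `pulldown`, `component`, `time_min`,
#' `amount_au`. Round-trips losslessly.
#'
#' @param path File path.
#' @return `read_stoich_series()`: a tibble; `write_stoich_series()`: `data`,
#'   invisibly.
#' @export
read_stoich_series <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    pulldown = readr::col_character(),
    component = readr::col_character(),
    time_min = readr::col_double(),
    amount_au = readr::col_double()
  ))
}

#' @rdname read_stoich_series
#' @param data Tibble with the four columns above.
#' @export
write_stoich_series <- function(data, path) {
  stopifnot(all(c("pulldown", "component", "time_min", "amount_au")
  %in% names(data)))
  readr::write_tsv(data[c("pulldown", "component", "time_min", "amount_au")],
    path
  )
  invisible(data)
}

#' Run manifest: everything needed to reproduce an output
#'
#' A small record of the model, overrides, solver settings, seed and package
#' version that produced an artifact; written alongside exports as JSON.
#'
#' @param model_id Model identifier.
#' @param overrides Named numeric overrides used (may be `NULL`).
#' @param solver List of solver settings (method, rtol, atol).
#' @param seed Seed, if any randomness was involved.
#' @param extra Optional named list of additional fields.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(model_id, overrides = NULL,
                         solver = list(
                           method = "lsoda", rtol = 1e-8,
                           atol = 1e-10
                         ),
                         seed = NULL, extra = list()) {
  structure(
    c(
      list(
        model_id = model_id,
        overrides = as.list(overrides),
        solver = solver,
        seed = seed,
        package_version = as.character(utils::packageVersion("myddosome")),
        timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
      ),
      extra
    ),
    class = "run_manifest"
  )
}

#' @rdname run_manifest
#' @param manifest A `run_manifest`.
#' @param path Output path (JSON).
#' @export
write_run_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path,
    auto_unbox = TRUE,
    pretty = TRUE, digits = NA
  )
  invisible(manifest)
}
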