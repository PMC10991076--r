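#' Write a kymograph as delimited text
#'
#' Tab-separated table: the header row carries the x-grid, the first
#' column the snapshot times, the body the densities.
#'
#' @param kymo a `kymograph`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_kymograph <- function(kymo, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("t", format(kymo$x, digits = 12, trim = TRUE)),
                   collapse = "\t"), con)
  utils::write.table(cbind(kymo$times, kymo$density), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a kymograph written by [write_kymograph()]
#'
#' @param path input path.
#' @return a `kymograph` (without configuration echo).
#' @export
read_kymograph <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  x <- as.numeric(header[-1L])
  body <- utils::read.table(path, sep = "\t", skip = 1L)
  new_kymograph(times = body[[1L]],
                x = x,
                rows = lapply(seq_len(nrow(body)), function(i)
                  as.numeric(body[i, -1L])),
                cfg = NULL)
}

#' Resolve a run configuration from a YAML file plus overrides
#'
#' Reads a flat YAML mapping whose keys mirror the model parameter names
#' (`D0`, `delta`, `chi0`, `theta`, `a`, `r`, `L`, `T`, `h`, `dt_outer`,
#' `inner_substeps`, `u0_level`, `mode`, `seed`, ...) and merges it with
#' command-line overrides (overrides win).
#'
#' @param config_path optional YAML path.
#' @param overrides named list of values overriding the file.
#' @return named list of resolved parameters.
#' @export
read_run_config <- function(config_path = NULL, overrides = list()) {
  base <- list()
  if (!is.null(config_path)) {
    if (!file.exists(config_path))
      stop(sprintf("config file not found: %s", config_path))
    base <- yaml::read_yaml(config_path)
    if (!is.list(base)) stop("config must be a YAML mapping")
  }
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  utils::modifyList(base, overrides)
}

#' Write a run manifest
#'
#' JSON record sufficient to reproduce a run: resolved parameters,
#' output paths, seed, wall time and package version.
#'
#' @param params named list of resolved parameters.
#' @param outputs named list/character of output paths.
#' @param seed integer seed or `NULL`.
#' @param wall_time_s elapsed seconds.
#' @param path manifest path.
#' @return the path, invisibly.
#' @export
write_manifest <- function(params, outputs, seed, wall_time_s, path) {
  manifest <- list(
    package = "adhesim",
    version = as.character(utils::packageVersion("adhesim")),
    seed = seed,
    wall_time_s = wall_time_s,
    parameters = params,
    outputs = outputs)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
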