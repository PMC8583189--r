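# CSV and config I/O for the site/participant/quantile schemas, plus the run
# manifest. Coordinates may arrive as projected x/y or as lon/lat; lon/lat
# are converted by an equirectangular local projection, which is adequate at
# city scale where only relative distances matter.

equirectangular_xy <- function(lon, lat) {
  r <- 6371000
  lat0 <- mean(lat) * pi / 180
  list(x = r * cos(lat0) * lon * pi / 180, y = r * lat * pi / 180)
}

resolve_coordinates <- function(df, name) {
  if (all(c("x", "y") %in% names(df))) return(df)
  if (all(c("lon", "lat") %in% names(df))) {
    xy <- equirectangular_xy(df$lon, df$lat)
    df$x <- xy$x
    df$y <- xy$y
    return(df)
  }
  stop_(sprintf("`%s` needs either x/y or lon/lat coordinate columns", name))
}

#' Read and write the site table
#'
#' The site CSV carries one row per site with `site_id`, `area`
#' (urban/rural), coordinates (`x`/`y` projected, or `lon`/`lat`), and the
#' annual total BaP_eq concentration `bap_eq` (ng m^-3).
#'
#' @param path CSV path.
#' @param sites Site data.frame.
#' @return `read_sites_csv` returns the validated site data.frame.
#' @export
read_sites_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("site_id", "bap_eq"), "sites")
  df <- resolve_coordinates(df, "sites")
  check_number(df$bap_eq, "bap_eq", nonneg = TRUE)
  if (anyDuplicated(df$site_id)) stop_("site ids must be unique")
  df
}

#' @rdname read_sites_csv
#' @export
write_sites_csv <- function(sites, path) {
  utils::write.csv(sites, path, row.names = FALSE)
  invisible(path)
}

#' Read and write the participant table
#'
#' One row per participant: `id`, `age` (years), `sex`, `area`, `height_cm`,
#' `bw_kg`, optionally `ir_lpm` (measured inhalation rate, L min^-1), and
#' either coordinates or a pre-assigned `site_id`.
#'
#' @param path CSV path.
#' @param participants Participant data.frame.
#' @return `read_participants_csv` returns the validated data.frame.
#' @export
read_participants_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop_("participant file is empty")
  check_columns(df, c("id", "age", "sex", "height_cm", "bw_kg"),
                "participants")
  if (!"site_id" %in% names(df)) df <- resolve_coordinates(df, "participants")
  check_number(df$bw_kg, "bw_kg", positive = TRUE)
  check_number(df$height_cm, "height_cm", positive = TRUE)
  df
}

#' @rdname read_participants_csv
#' @export
write_participants_csv <- function(participants, path) {
  utils::write.csv(participants, path, row.names = FALSE)
  invisible(path)
}

#' Read a handbook quantile table
#'
#' Long format: `stratum`, `parameter` (`bw` or `ir`), `p`, `value`.
#'
#' @param path CSV path.
#' @return Validated data.frame.
#' @export
read_quantiles_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("stratum", "parameter", "p", "value"), "quantiles")
  if (any(df$p <= 0 | df$p >= 1)) stop_("probabilities must lie in (0, 1)")
  check_number(df$value, "value", positive = TRUE)
  df
}

#' Fit lognormals to every stratum/parameter block of a quantile table
#'
#' @param quantiles Long quantile table as from [read_quantiles_csv()] or
#'   [gen_handbook_quantiles()].
#' @return Nested list: `fits[[stratum]][[parameter]]` is a
#'   [lognormal_params()].
#' @export
fit_quantile_table <- function(quantiles) {
  check_columns(quantiles, c("stratum", "parameter", "p", "value"),
                "quantiles")
  out <- list()
  for (s in unique(quantiles$stratum)) {
    out[[s]] <- list()
    for (par in unique(quantiles$parameter[quantiles$stratum == s])) {
      block <- quantiles[quantiles$stratum == s & quantiles$parameter == par, ]
      block <- block[order(block$p), ]
      out[[s]][[par]] <- fit_lognormal_quantiles(
        quantile_set(block$p, block$value))
    }
  }
  out
}

#' Read a TEF table from a two-column CSV
#'
#' Columns `congener`, `tef`.
#'
#' @param path CSV path.
#' @param allow_extra Accept congeners beyond the default fifteen.
#' @return A [tef_table()].
#' @export
read_tef_csv <- function(path, allow_extra = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("congener", "tef"), "tefs")
  tef_table(stats::setNames(df$tef, df$congener), allow_extra = allow_extra)
}

#' Read a scenario configuration file
#'
#' YAML (or JSON, which YAML subsumes) with optional blocks `constants`
#' (ef, ed, at, csf), `tefs` (congener: tef), and `distributions`
#' (named blocks with `meanlog`, `sdlog`). Missing blocks fall back to the
#' package defaults.
#'
#' @param path Config file path.
#' @return List with elements `constants` ([exposure_constants()]), `tefs`
#'   ([tef_table()]), `distributions` (named list of [lognormal_params()])
#'   and `raw` (the parsed file).
#' @export
read_scenario_config <- function(path) {
  raw <- yaml::read_yaml(path)
  constants <- if (!is.null(raw$constants)) {
    do.call(exposure_constants, raw$constants)
  } else {
    exposure_constants()
  }
  tefs <- if (!is.null(raw$tefs)) {
    tef_table(unlist(raw$tefs))
  } else {
    default_tef_table()
  }
  dists <- list()
  for (nm in names(raw$distributions)) {
    d <- raw$distributions[[nm]]
    dists[[nm]] <- lognormal_params(d$meanlog, d$sdlog)
  }
  list(constants = constants, tefs = tefs, distributions = dists, raw = raw)
}

#' Write a run manifest
#'
#' Records the seed, package version, timestamp, a stable hash of the
#' configuration, and every artifact a command emitted.
#'
#' @param dir Output directory.
#' @param files Character vector of emitted file paths (relative to `dir`).
#' @param seed Seed used.
#' @param config Any serializable configuration object.
#' @return Path of the manifest file, invisibly.
#' @export
write_run_manifest <- function(dir, files, seed, config = NULL) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  manifest <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("pahrisk")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_hash = unname(tools::md5sum(tmp)),
    artifacts = as.list(files)
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
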