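#' Read a modern calibration table
#'
#' One row per modern cereal-grain sample with a measured d15N value
#' (permil vs AIR), the site's mean annual rainfall (mm/yr) and the known
#' manuring level. Level strings are matched case-insensitively against
#' `low`/`medium`/`high` (also accepts `l`/`m`/`h` and `1`/`2`/`3`) and
#' stored as an ordered factor low < medium < high. Extra columns are
#' preserved untouched.
#'
#' @param path Path to a comma-separated UTF-8 file with one header row and
#'   at least the columns `d15n`, `rainfall_mm`, `level`.
#' @return A tibble with columns `d15n` (double), `rainfall_mm` (double),
#'   `level` (ordered factor) plus any extra columns, in input order.
#' @seealso [generate_modern()] to simulate such a table, [fit_calibration()]
#'   to fit the d15N-rainfall model to it.
#' @export
read_modern_table <- function(path) {
  df <- read_csv_strict(path, c("d15n", "rainfall_mm", "level"))
  if (nrow(df) == 0) {
    warn("Modern table has a header but no data rows.")
    return(dplyr::mutate(df,
                         d15n = double(), rainfall_mm = double(),
                         level = factor(character(), .levels, ordered = TRUE)))
  }

  lev <- parse_level(df$level)
  problems <- character()
  bad_lev <- which(is.na(lev) & !is.na(df$level))
  if (length(bad_lev) > 0) {
    problems <- c(problems, sprintf(
      "row %d: unparseable manuring level '%s'", bad_lev, df$level[bad_lev]))
  }
  problems <- c(problems,
                check_numeric(df$d15n, "d15n"),
                check_numeric(df$rainfall_mm, "rainfall_mm", positive = TRUE))
  raise_validation(problems, path)

  df$level <- lev
  df$d15n <- as.numeric(df$d15n)
  df$rainfall_mm <- as.numeric(df$rainfall_mm)
  df
}

#' Read an archaeological sample table
#'
#' One row per charred cereal-grain sample: identifiers (`sample_id`,
#' `region`, `site`, `phase`), covariates (`date_calBC` midpoint in years BC,
#' larger = older; `size_ha` settlement size in hectares), the normalised,
#' charring-corrected d15N value, and a past-rainfall range
#' `[rain_min_mm, rain_max_mm]` in mm/yr. A `taxon` column, if present, is
#' carried as metadata, as are any other extra columns. If `date_calBC` is
#' absent but `date_min_calBC` and `date_max_calBC` are present, the midpoint
#' is computed.
#'
#' All invariant violations (non-positive sizes or rainfall, inverted
#' rainfall ranges, duplicate sample ids, sites spanning multiple regions)
#' are collected and reported together, not one at a time.
#'
#' @param path Path to a comma-separated UTF-8 file with one header row.
#' @return A tibble with the columns above (identifiers as character), in
#'   input order.
#' @export
read_arch_table <- function(path) {
  need <- c("sample_id", "region", "site", "phase", "size_ha", "d15n",
            "rain_min_mm", "rain_max_mm")
  df <- read_csv_strict(path, need, optional_one_of = list(
    date = c("date_calBC", "date_min_calBC|date_max_calBC")))

  if (!("date_calBC" %in% names(df))) {
    if (all(c("date_min_calBC", "date_max_calBC") %in% names(df))) {
      df$date_calBC <- (as.numeric(df$date_min_calBC) +
                          as.numeric(df$date_max_calBC)) / 2
    } else {
      abort(paste0("Missing required column(s) in ", path,
                   ": date_calBC (or date_min_calBC + date_max_calBC)"))
    }
  }
  if (nrow(df) == 0) {
    warn("Archaeological table has a header but no data rows.")
    return(df)
  }

  problems <- c(
    check_numeric(df$size_ha, "size_ha", positive = TRUE),
    check_numeric(df$d15n, "d15n"),
    check_numeric(df$date_calBC, "date_calBC"),
    check_numeric(df$rain_min_mm, "rain_min_mm", positive = TRUE),
    check_numeric(df$rain_max_mm, "rain_max_mm", positive = TRUE)
  )
  inverted <- which(is.finite(as.numeric(df$rain_min_mm)) &
                      is.finite(as.numeric(df$rain_max_mm)) &
                      as.numeric(df$rain_min_mm) > as.numeric(df$rain_max_mm))
  if (length(inverted) > 0) {
    problems <- c(problems, sprintf(
      "row %d: rain_min_mm (%s) exceeds rain_max_mm (%s)",
      inverted, df$rain_min_mm[inverted], df$rain_max_mm[inverted]))
  }
  dup <- which(duplicated(df$sample_id))
  if (length(dup) > 0) {
    problems <- c(problems, sprintf(
      "row %d: duplicate sample_id '%s'", dup, df$sample_id[dup]))
  }
  site_regions <- tapply(df$region, df$site, function(r) length(unique(r)))
  multi <- names(site_regions)[site_regions > 1]
  if (length(multi) > 0) {
    problems <- c(problems, sprintf(
      "site '%s' appears in more than one region", multi))
  }
  raise_validation(problems, path)

  for (col in c("size_ha", "d15n", "date_calBC", "rain_min_mm", "rain_max_mm")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  for (col in c("sample_id", "region", "site", "phase")) {
    df[[col]] <- as.character(df[[col]])
  }
  if (!("taxon" %in% names(df))) df$taxon <- NA_character_
  df
}

#' Write modern or archaeological tables to CSV
#'
#' Inverse of [read_modern_table()] / [read_arch_table()]: values round-trip
#' exactly up to decimal formatting.
#'
#' @param data A tibble as returned by the reader or generator functions.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_modern_table <- function(data, path) {
  out <- data
  out$level <- as.character(out$level)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_modern_table
#' @export
write_arch_table <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

# ---- internal helpers -------------------------------------------------------

read_csv_strict <- function(path, required, optional_one_of = NULL) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0("Missing required column(s) in ", path, ": ",
                 paste(missing, collapse = ", ")))
  }
  tibble::as_tibble(df)
}

parse_level <- function(x) {
  key <- tolower(trimws(as.character(x)))
  idx <- match(key, .levels)
  idx[is.na(idx)] <- match(key[is.na(idx)], c("l", "m", "h"))
  idx[is.na(idx)] <- match(key[is.na(idx)], c("1", "2", "3"))
  factor(.levels[idx], levels = .levels, ordered = TRUE)
}

check_numeric <- function(x, name, positive = FALSE) {
  v <- suppressWarnings(as.numeric(x))
  problems <- character()
  bad <- which(!is.finite(v))
  if (length(bad) > 0) {
    problems <- c(problems, sprintf(
      "row %d: %s is not a finite number ('%s')", bad, name, x[bad]))
  }
  if (positive) {
    nonpos <- which(is.finite(v) & v <= 0)
    if (length(nonpos) > 0) {
      problems <- c(problems, sprintf(
        "row %d: %s must be > 0 (got %s)", nonpos, name, x[nonpos]))
    }
  }
  problems
}

raise_validation <- function(problems, path) {
  if (length(problems) > 0) {
    abort(paste0("Validation of ", path, " failed:\n",
                 paste0("  - ", problems, collapse = "\n")))
  }
  invisible(NULL)
}
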