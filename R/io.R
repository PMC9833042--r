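#' Read and write gas-exchange curve files
#'
#' Curves travel as tab-delimited text emulating open-system cuvette logs:
#' a block of `# key: value` metadata lines (plant_id, growth, measurement,
#' r_d, rubisco_sites) followed by a header row and one row per CO2 step.
#' Column matching is case-insensitive; row order is preserved.
#'
#' @param path File path.
#' @return `read_gas_exchange()` returns a [gas_exchange_curve()];
#'   `write_gas_exchange()` returns `path` invisibly.
#' @export
read_gas_exchange <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("gas-exchange file not found: %s", path),
          class = "rubiscotherm_io_error")
  }
  lines <- readr::read_lines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list(plant_id = "plant1", growth = "", measurement = NA_real_,
               r_d = 0, rubisco_sites = NA_real_)
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)\\s*$", ln))[[1]]
    if (length(m) == 3L && m[2] %in% names(meta)) {
      val <- m[3]
      meta[[m[2]]] <- if (m[2] %in% c("measurement", "r_d", "rubisco_sites")) {
        suppressWarnings(as.numeric(val))
      } else {
        val
      }
    }
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) {
    abort(sprintf("no data rows in '%s'.", path), class = "rubiscotherm_io_error")
  }
  header <- tolower(strsplit(body[1], "\t", fixed = TRUE)[[1]])
  missing <- setdiff(ge_columns, header)
  if (length(missing)) {
    abort(sprintf("'%s' is missing required column(s): %s",
                  path, paste(missing, collapse = ", ")),
          class = "rubiscotherm_schema_error")
  }
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  parsed <- lapply(seq_along(rows), function(i) {
    vals <- suppressWarnings(as.numeric(rows[[i]]))
    bad <- which(is.na(vals) & !(rows[[i]] %in% c("NA", "")))
    if (length(bad)) {
      abort(sprintf("non-numeric value '%s' in column '%s', data row %d of '%s'.",
                    rows[[i]][bad[1]], header[bad[1]], i, path),
            class = "rubiscotherm_parse_error")
    }
    vals
  })
  tbl <- as_tibble(setNames(as.data.frame(do.call(rbind, parsed)), header))
  gas_exchange_curve(
    dplyr::select(tbl, dplyr::all_of(ge_columns)),
    plant_id = meta$plant_id, growth = meta$growth,
    measurement = meta$measurement, r_d = meta$r_d,
    rubisco_sites = meta$rubisco_sites
  )
}

#' @rdname read_gas_exchange
#' @param curve A [gas_exchange_curve()].
#' @export
write_gas_exchange <- function(curve, path) {
  validate_gas_exchange(curve)
  meta <- curve_meta(curve)
  header <- c(
    sprintf("# plant_id: %s", meta$plant_id),
    sprintf("# growth: %s", meta$growth),
    sprintf("# measurement: %s", format_num(meta$measurement)),
    sprintf("# r_d: %s", format_num(meta$r_d)),
    sprintf("# rubisco_sites: %s", format_num(meta$rubisco_sites))
  )
  body <- vapply(
    seq_len(nrow(curve)),
    function(i) paste(vapply(ge_columns, function(cl) format_num(curve[[cl]][i]),
                             character(1)), collapse = "\t"),
    character(1)
  )
  readr::write_lines(c(header, paste(ge_columns, collapse = "\t"), body), path)
  invisible(path)
}

## Deterministic 6-significant-digit formatting so reports diff cleanly.
format_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "NA"
    else if (is.character(v)) v
    else format(signif(v, 6), scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
  }, character(1))
}

#' Write a result table as a clean delimited report
#'
#' Tab-separated, deterministic column order (as given), numbers at 6
#' significant digits, optional `# key: value` header lines. Two runs with
#' the same inputs produce byte-identical files.
#'
#' @param results Data frame of results.
#' @param path Output path.
#' @param header Optional named list written as `# key: value` lines.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, header = NULL) {
  if (!is.data.frame(results)) {
    abort("`results` must be a data frame.", class = "rubiscotherm_input_error")
  }
  head_lines <- if (length(header)) {
    vapply(names(header), function(k) sprintf("# %s: %s", k, format_num(header[[k]])),
           character(1))
  } else {
    character(0)
  }
  body <- vapply(
    seq_len(nrow(results)),
    function(i) paste(vapply(names(results), function(cl) {
      v <- results[[cl]][i]
      if (is.numeric(v)) format_num(v) else as.character(v)
    }, character(1)), collapse = "\t"),
    character(1)
  )
  out <- tryCatch(
    readr::write_lines(c(head_lines, paste(names(results), collapse = "\t"), body), path),
    error = function(e) {
      abort(sprintf("cannot write report to '%s': %s", path, conditionMessage(e)),
            class = "rubiscotherm_io_error")
    }
  )
  invisible(path)
}

#' Read a report written by [write_report()]
#'
#' @param path Report path.
#' @return Tibble (comment lines skipped).
#' @export
read_report <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}

run_config_spec <- list(
  o2_mole_fraction = list(default = 210000, check = function(x) x > 0 && x < 1e6),
  pressure_kpa = list(default = 101.325, check = function(x) x > 10 && x < 200),
  seed = list(default = 1L, check = function(x) x == round(x) && abs(x) < 2^31),
  replicates = list(default = 5L, check = function(x) x == round(x) && x >= 1),
  noise_sd_gas = list(default = 0.2, check = function(x) x >= 0),
  noise_cv_assay = list(default = 0.05, check = function(x) x >= 0 && x < 1),
  ci_ca_ratio = list(default = 0.7, check = function(x) x > 0 && x < 1),
  normalise_by_sites = list(default = TRUE, check = is.logical),
  plot_gross = list(default = FALSE, check = is.logical),
  kinetics_table = list(default = NA_character_, check = is.character),
  solubility_table = list(default = NA_character_, check = is.character),
  input_dir = list(default = NA_character_, check = is.character),
  output_dir = list(default = NA_character_, check = is.character)
)

#' Load and validate a run configuration
#'
#' YAML key-value file controlling a pipeline run. Unknown keys are
#' rejected; every numeric field is bounds-checked. Missing keys take the
#' documented defaults.
#'
#' @param path Path to a YAML config, or `NULL` for pure defaults.
#' @return Named list of validated settings.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- lapply(run_config_spec, function(s) s$default)
  if (!is.null(path)) {
    if (!file.exists(path)) {
      abort(sprintf("config file not found: %s", path), class = "rubiscotherm_io_error")
    }
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(run_config_spec))
    if (length(unknown)) {
      abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
            class = "rubiscotherm_config_error")
    }
    for (k in names(user)) {
      v <- user[[k]]
      if (!isTRUE(run_config_spec[[k]]$check(v))) {
        abort(sprintf("config key '%s' has an invalid value: %s", k, format(v)),
              class = "rubiscotherm_config_error")
      }
      cfg[[k]] <- v
    }
  }
  cfg
}
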