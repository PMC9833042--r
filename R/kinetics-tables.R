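#' Read and write Rubisco kinetics tables
#'
#' Delimited-text interchange format for sets of Rubisco kinetic constants:
#' one row per (growth label, parameter), columns `label`, `parameter`
#' (`kcat_co2`, `s_co`, `k_c`, `k_o`), `value_25`, `se_25`, `ea_kj_mol`,
#' `se_ea`. `#`-prefixed lines are comments.
#'
#' @param path File path.
#' @return `read_kinetics_table()` returns the table as a tibble;
#'   `write_kinetics_table()` returns `path` invisibly.
#' @seealso [as_rubisco_kinetics()], [arabidopsis_kinetics()]
#' @export
read_kinetics_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("kinetics table not found: %s", path), class = "rubiscotherm_io_error")
  }
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  need <- c("label", "parameter", "value_25", "se_25", "ea_kj_mol", "se_ea")
  missing <- setdiff(need, names(tbl))
  if (length(missing)) {
    abort(sprintf("kinetics table is missing column(s): %s", paste(missing, collapse = ", ")),
          class = "rubiscotherm_schema_error")
  }
  bad <- setdiff(unique(tbl$parameter), c("kcat_co2", "s_co", "k_c", "k_o"))
  if (length(bad)) {
    abort(sprintf("unknown kinetic parameter(s): %s", paste(bad, collapse = ", ")),
          class = "rubiscotherm_schema_error")
  }
  tbl
}

#' @rdname read_kinetics_table
#' @param tbl Kinetics table (as from [read_kinetics_table()]).
#' @export
write_kinetics_table <- function(tbl, path) {
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Build a `rubisco_kinetics` object from a kinetics table
#'
#' @param tbl Kinetics table tibble (see [read_kinetics_table()]).
#' @param label Growth label to extract, e.g. `"10C"`.
#' @return A [rubisco_kinetics()] object.
#' @export
as_rubisco_kinetics <- function(tbl, label) {
  rows <- tbl[tbl$label == label, ]
  if (nrow(rows) == 0L) {
    abort(sprintf("label '%s' not present in the kinetics table.", label),
          class = "rubiscotherm_input_error")
  }
  get_tr <- function(p) {
    r <- rows[rows$parameter == p, ]
    if (nrow(r) != 1L) {
      abort(sprintf("label '%s' needs exactly one '%s' row.", label, p),
            class = "rubiscotherm_input_error")
    }
    temperature_response(r$value_25, r$ea_kj_mol, r$se_25, r$se_ea)
  }
  rubisco_kinetics(
    kcat_co2 = get_tr("kcat_co2"), s_co = get_tr("s_co"),
    k_c = get_tr("k_c"), k_o = get_tr("k_o"), label = label
  )
}

#' Bundled Arabidopsis growth-temperature Rubisco kinetics
#'
#' Treatment-mean kinetic constants (25 degC values and activation energies)
#' for Arabidopsis grown at 10, 20 and 30 degC, shipped as a plain-text
#' fixture.
#'
#' @param label Optional growth label (`"10C"`, `"20C"`, `"30C"`). If given,
#'   returns that treatment's [rubisco_kinetics()]; otherwise the full table.
#' @return A tibble or a [rubisco_kinetics()] object.
#' @examples
#' arabidopsis_kinetics("10C")
#' @export
arabidopsis_kinetics <- function(label = NULL) {
  tbl <- read_kinetics_table(
    system.file("extdata", "rubisco_kinetics_arabidopsis.tsv", package = "rubiscotherm")
  )
  if (is.null(label)) tbl else as_rubisco_kinetics(tbl, label)
}

#' Bundled treatment-mean photosynthetic parameters and leaf traits
#'
#' `photosynthesis_defaults()` returns the per-cell (growth x measurement
#' temperature) gas-exchange parameter means used as the default generating
#' truth of the synthetic study; `leaf_traits()` returns per-growth-treatment
#' leaf composition means (Rubisco sites, soluble protein, chlorophyll).
#'
#' @return A tibble.
#' @export
photosynthesis_defaults <- function() {
  readr::read_tsv(
    system.file("extdata", "photosynthesis_defaults.tsv", package = "rubiscotherm"),
    comment = "#", show_col_types = FALSE
  )
}

#' @rdname photosynthesis_defaults
#' @export
leaf_traits <- function() {
  readr::read_tsv(
    system.file("extdata", "leaf_traits_arabidopsis.tsv", package = "rubiscotherm"),
    comment = "#", show_col_types = FALSE
  )
}
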