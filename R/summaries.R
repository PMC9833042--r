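#' Percent difference between two treatment means
#'
#' Two conventions used when contrasting treatment means: `"reduction"`
#' expresses how much smaller `other` is than `reference`
#' (`100 (reference - other) / reference`, "X% less"), `"excess"` expresses
#' how much larger `reference` is than `other`
#' (`100 (reference - other) / other`, "X% greater").
#'
#' @param reference,other Treatment means (vectorised).
#' @param mode `"reduction"` or `"excess"`.
#' @return Percent difference(s).
#' @examples
#' percent_difference(14.4, 8.9, "reduction") # ~ 38% less
#' percent_difference(24.6, 19.8, "excess")   # ~ 24% larger
#' @export
percent_difference <- function(reference, other, mode = c("reduction", "excess")) {
  mode <- match.arg(mode)
  base <- if (mode == "reduction") reference else other
  if (any(base == 0)) {
    abort("the comparison base must be non-zero.", class = "rubiscotherm_domain_error")
  }
  100 * (reference - other) / base
}

#' Group means and standard errors of fitted parameters
#'
#' Summarises a tidy table of per-plant results (one row per plant, one
#' column per parameter) into treatment-cell means and standard errors,
#' mirroring how gas-exchange studies report fitted photosynthetic
#' parameters.
#'
#' @param data Data frame of per-plant values.
#' @param ... Grouping columns (tidy-eval), e.g. `growth, measurement`.
#' @return Tibble in long form: grouping columns, `parameter`, `mean`, `se`,
#'   `n`.
#' @export
summarize_fits <- function(data, ...) {
  grouped <- dplyr::group_by(data, ...)
  value_cols <- setdiff(
    names(data)[vapply(data, is.numeric, logical(1))],
    dplyr::group_vars(grouped)
  )
  long <- tidyr::pivot_longer(
    grouped,
    cols = dplyr::all_of(value_cols),
    names_to = "parameter", values_to = "value"
  )
  dplyr::summarise(
    dplyr::group_by(long, .data$parameter, .add = TRUE),
    mean = mean(.data$value, na.rm = TRUE),
    se = sd(.data$value, na.rm = TRUE) / sqrt(sum(is.finite(.data$value))),
    n = sum(is.finite(.data$value)),
    .groups = "drop"
  )
}

#' Growth-treatment contrasts of summarised parameters
#'
#' Turns a [summarize_fits()] table into cold-vs-warm percent differences
#' per parameter (and per any remaining grouping column, e.g. measurement
#' temperature).
#'
#' @param summary_tbl Output of [summarize_fits()] with a `growth` column.
#' @param reference,other Growth labels for the two treatments being
#'   contrasted (reference first, e.g. cold-grown).
#' @param mode Passed to [percent_difference()].
#' @return Tibble with the retained grouping columns, `parameter`,
#'   `reference_mean`, `other_mean`, `percent`.
#' @export
contrast_growth <- function(summary_tbl, reference = "10C", other = "30C",
                            mode = c("excess", "reduction")) {
  mode <- match.arg(mode)
  need <- c("growth", "parameter", "mean")
  missing <- setdiff(need, names(summary_tbl))
  if (length(missing)) {
    abort(sprintf("summary table is missing column(s): %s", paste(missing, collapse = ", ")),
          class = "rubiscotherm_schema_error")
  }
  keys <- setdiff(names(summary_tbl), c("growth", "mean", "se", "n"))
  ref <- dplyr::filter(summary_tbl, .data$growth == reference)
  oth <- dplyr::filter(summary_tbl, .data$growth == other)
  joined <- dplyr::inner_join(
    dplyr::select(ref, dplyr::all_of(keys), reference_mean = "mean"),
    dplyr::select(oth, dplyr::all_of(keys), other_mean = "mean"),
    by = keys
  )
  dplyr::mutate(
    joined,
    percent = percent_difference(.data$reference_mean, .data$other_mean, mode)
  )
}
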