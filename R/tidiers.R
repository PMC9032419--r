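#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a karyotype into its segment table
#'
#' @param x A `"karyotype"` object from [call_karyotype()].
#' @param ... Unused.
#' @return Tibble of called segments (one row per segment).
#' @exportS3Method generics::tidy
tidy.karyotype <- function(x, ...) {
  x$segments
}

#' One-row summary of a karyotype
#'
#' @param x A `"karyotype"` object.
#' @param ... Unused.
#' @return Tibble: `n_chromosomes`, `total_cn` (sum of modal copy
#'   numbers), `n_breakpoints` (segment boundaries with a copy-number
#'   change), `haploid_unit`.
#' @exportS3Method generics::glance
glance.karyotype <- function(x, ...) {
  n_bp <- x$segments |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(b = sum(diff(.data$cn) != 0), .groups = "drop")
  tibble::tibble(
    n_chromosomes = nrow(x$chromosomes),
    total_cn = attr(x$chromosomes, "total_cn"),
    n_breakpoints = sum(n_bp$b),
    haploid_unit = x$unit
  )
}

#' Tidy a dosage regression into its category table
#'
#' @param x A `"dosage_regression"` object.
#' @param ... Unused.
#' @return Per-category tibble: `category`, `log2_ratio`, `n`, `mean`,
#'   `sem`.
#' @exportS3Method generics::tidy
tidy.dosage_regression <- function(x, ...) {
  x$categories
}

#' One-row summary of a dosage regression
#'
#' @param x A `"dosage_regression"` object.
#' @param ... Unused.
#' @return Tibble: `slope`, `intercept`, `r_squared`, `p_value`,
#'   `n_pairs`, `n_categories`, `n_excluded_zero_cn`, plus the unbinned
#'   `slope_unbinned` and `r_squared_unbinned`.
#' @exportS3Method generics::glance
glance.dosage_regression <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
    p_value = x$p_value, n_pairs = x$n_pairs,
    n_categories = nrow(x$categories),
    n_excluded_zero_cn = x$n_excluded_zero_cn,
    slope_unbinned = x$unbinned$slope,
    r_squared_unbinned = x$unbinned$r_squared
  )
}
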