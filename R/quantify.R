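#' Fractional abundance of co-eluting species
#'
#' Each intensity divided by the group total (the paper-style "peak
#' intensity over total biotransformation peak intensity"). An all-zero
#' group returns all zeros with a warning: samples with no observed signal
#' are plotted as zero rather than dropped.
#'
#' @param intensities non-negative numeric vector.
#' @return fractions summing to 1 (or all zero).
#' @export
#' @examples
#' fractional_abundance(c(80, 20))
fractional_abundance <- function(intensities) {
  if (any(intensities < 0)) abort("intensities must be non-negative")
  total <- sum(intensities)
  if (total == 0) {
    warn("all intensities are zero; returning zero fractions")
    return(rep(0, length(intensities)))
  }
  intensities / total
}

#' Percent difference between two measurements
#'
#' Signed difference over the mean of the two, times 100. The default sign
#' convention is new minus old; `sign = "old_minus_new"` flips it.
#'
#' @param new_value,old_value numeric vectors.
#' @param sign `"new_minus_old"` (default) or `"old_minus_new"`.
#' @return percent difference; `NA` where both values are zero.
#' @export
#' @examples
#' percent_difference(0.25, 0.20)  # +22.22
percent_difference <- function(new_value, old_value,
                               sign = c("new_minus_old", "old_minus_new")) {
  sign <- match.arg(sign)
  m <- (new_value + old_value) / 2
  d <- if (sign == "new_minus_old") new_value - old_value else old_value - new_value
  out <- d / m * 100
  out[m == 0] <- NA_real_
  out
}

#' Per-sample fractional abundances from a consolidated species table
#'
#' Fractions are computed within each (sample, chain) group over the
#' annotated species (the per-chain biotransformation total).
#'
#' @param species_table tibble from [consolidate()] (columns `species`,
#'   `sample_id`, `subject`, `time_h`, `intensity`, optionally
#'   `chain_id`).
#' @param include_unidentified include "unidentified" species in the
#'   denominator (default FALSE).
#' @return the table with a `fraction` column added.
#' @export
per_sample_fractions <- function(species_table, include_unidentified = FALSE) {
  x <- species_table
  if (!include_unidentified) {
    x <- x[!grepl("^unidentified", x$species), ]
  }
  grp <- intersect(c("sample_id", "chain_id"), names(x))
  x |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(fraction = {
      tot <- sum(.data$intensity)
      if (tot == 0) rep(0, dplyr::n()) else .data$intensity / tot
    }) |>
    dplyr::ungroup()
}

#' Aggregate subject-level fractions into a time course
#'
#' Mean and sample standard deviation (n - 1 denominator; a single subject
#' gives sd 0) per species and time point.
#'
#' @param per_subject tibble with `species`, `subject`, `time_h`,
#'   `fraction` (and optionally `chain_id`), one row per subject.
#' @return object of class `adc_timecourse`: a tibble with `species`,
#'   `time_h`, `mean_fraction`, `sd_fraction`, `n_subjects` (plus
#'   `chain_id` when present), carrying the per-subject data as an
#'   attribute.
#' @export
aggregate_replicates <- function(per_subject) {
  grp <- intersect(c("chain_id", "species", "time_h"), names(per_subject))
  out <- per_subject |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      mean_fraction = mean(.data$fraction),
      sd_fraction = if (dplyr::n() > 1L) sd(.data$fraction) else 0,
      n_subjects = dplyr::n(),
      .groups = "drop"
    )
  attr(out, "per_subject") <- per_subject
  class(out) <- c("adc_timecourse", class(out))
  out
}

#' Quantify a longitudinal biotransformation time course
#'
#' Convenience wrapper: consolidated species table -> per-sample fractions
#' -> replicate-aggregated time course.
#'
#' @inheritParams per_sample_fractions
#' @inheritParams consolidate
#' @export
quantify_timecourse <- function(species_table, include_unidentified = FALSE) {
  per_sample_fractions(species_table, include_unidentified) |>
    aggregate_replicates()
}

#' @export
print.adc_timecourse <- function(x, ...) {
  cat("<adc_timecourse> ", dplyr::n_distinct(x$species), " species x ",
      dplyr::n_distinct(x$time_h), " time points\n", sep = "")
  NextMethod()
}

#' Tidy a biotransformation time course
#'
#' One row per species x time point with mean, sd and n.
#'
#' @param x an `adc_timecourse`.
#' @param ... unused.
#' @method tidy adc_timecourse
#' @export
tidy.adc_timecourse <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "adc_timecourse")
  attr(out, "per_subject") <- NULL
  tibble::as_tibble(out)
}

#' One-row summary of a time course
#'
#' @param x an `adc_timecourse`.
#' @param ... unused.
#' @method glance adc_timecourse
#' @export
glance.adc_timecourse <- function(x, ...) {
  tibble::tibble(
    n_species = dplyr::n_distinct(x$species),
    n_timepoints = dplyr::n_distinct(x$time_h),
    n_subjects = max(x$n_subjects),
    max_sd = max(x$sd_fraction)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
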