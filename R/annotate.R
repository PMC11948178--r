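#' Parts-per-million mass accuracy
#'
#' @param observed observed neutral mass in Da.
#' @param theoretical theoretical mass in Da; must be positive.
#' @return signed ppm, `(observed - theoretical) / theoretical * 1e6`.
#' @export
#' @examples
#' compute_ppm(24757.85, 24758)  # about -6 ppm
compute_ppm <- function(observed, theoretical) {
  if (any(theoretical <= 0)) abort("theoretical mass must be positive")
  (observed - theoretical) / theoretical * 1e6
}

#' Match deconvoluted mass peaks to proteoform candidates
#'
#' Every candidate within the absolute mass tolerance of a peak is
#' returned, ranked by |ppm| (ties broken by lower theoretical mass).
#' Peaks with several in-tolerance candidates are flagged for manual
#' review rather than auto-resolved; peaks with none yield an
#' "unidentified" record. When both tables carry a `chain_id` column
#' (peaks inherit it from their retention-time window), matching is
#' restricted per chain.
#'
#' @param peaks tibble with `neutral_mass`, `intensity`, optionally
#'   `chain_id` and sample columns.
#' @param candidates tibble from [enumerate_candidates()].
#' @param tolerance_da absolute mass tolerance in Da (default 3, boundary
#'   inclusive).
#' @param scale which theoretical mass scale to match against:
#'   `"average"` (default; deconvolved intact masses are isotopically
#'   unresolved) or `"monoisotopic"`.
#' @return tibble with one row per (peak, matched candidate) plus
#'   unidentified rows: peak columns, `label`, `theo_mass`, `delta_da`,
#'   `ppm`, `rank`, `n_alternatives`, `review_flag`.
#' @export
match_peaks <- function(peaks, candidates, tolerance_da = 3,
                        scale = c("average", "monoisotopic")) {
  scale <- match.arg(scale)
  if (!nrow(candidates)) abort("empty candidate set")
  stopifnot(tolerance_da > 0)
  theo_col <- if (scale == "average") "theo_avg_mass" else "theo_mono_mass"
  by_chain <- "chain_id" %in% names(peaks) && "chain_id" %in% names(candidates)
  out <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    pk <- peaks[i, ]
    cand <- candidates
    if (by_chain) cand <- cand[cand$chain_id == pk$chain_id, ]
    theo <- cand[[theo_col]]
    hit <- which(abs(pk$neutral_mass - theo) <= tolerance_da)
    if (!length(hit)) {
      out[[i]] <- dplyr::bind_cols(pk, tibble::tibble(
        label = NA_character_, theo_mass = NA_real_, delta_da = NA_real_,
        ppm = NA_real_, rank = NA_integer_, n_alternatives = 0L,
        review_flag = FALSE))
      next
    }
    ppm <- compute_ppm(pk$neutral_mass, theo[hit])
    # rank by absolute mass error; exact ties go to the lower theoretical
    # mass (for a single peak this orders |ppm| identically except when the
    # Da errors tie exactly)
    ord <- order(abs(pk$neutral_mass - theo[hit]), theo[hit])
    hit <- hit[ord]
    ppm <- ppm[ord]
    out[[i]] <- dplyr::bind_cols(
      pk[rep(1L, length(hit)), ],
      tibble::tibble(
        label = cand$label[hit],
        theo_mass = theo[hit],
        delta_da = pk$neutral_mass - theo[hit],
        ppm = ppm,
        rank = seq_along(hit),
        n_alternatives = length(hit),
        review_flag = length(hit) > 1L
      ))
  }
  dplyr::bind_rows(out)
}

#' Keep species reproducibly observed across PK time points
#'
#' A species (annotation label, or the rounded mass for unidentified
#' peaks) is retained only when observed in at least
#' `min_timepoint_fraction` of the time points (boundary inclusive); the
#' output has one row per retained species x sample with intensity 0 where
#' the species was absent.
#'
#' @param annotations tibble from [match_peaks()] with `sample_id`,
#'   `subject`, `time_h`, `intensity` columns; rank-1 rows are used when a
#'   peak has multiple assignments.
#' @param min_timepoint_fraction minimum fraction of time points (default
#'   0.5).
#' @return tibble with `species`, `chain_id` (if present), `sample_id`,
#'   `subject`, `time_h`, `intensity`.
#' @export
consolidate <- function(annotations, min_timepoint_fraction = 0.5) {
  x <- annotations
  if (!all(c("sample_id", "time_h") %in% names(x))) {
    abort("annotations need sample_id and time_h columns")
  }
  x <- x[is.na(x$rank) | x$rank == 1L, ]
  x$species <- ifelse(is.na(x$label),
                      paste0("unidentified m/", round(x$neutral_mass)),
                      x$label)
  has_chain <- "chain_id" %in% names(x)
  has_subject <- "subject" %in% names(x)
  n_tp <- length(unique(x$time_h))
  keep <- x |>
    dplyr::filter(.data$intensity > 0) |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(n_present = dplyr::n_distinct(.data$time_h)) |>
    dplyr::filter(.data$n_present / n_tp >= min_timepoint_fraction)
  x <- x[x$species %in% keep$species, ]
  samples <- dplyr::distinct(
    annotations[, intersect(c("sample_id", "subject", "time_h"), names(annotations))])
  grid_cols <- c("species", if (has_chain) "chain_id")
  species_tbl <- dplyr::distinct(x[, grid_cols, drop = FALSE])
  grid <- tidyr::crossing(species_tbl, samples)
  obs <- x |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grid_cols, "sample_id")))) |>
    dplyr::summarise(intensity = sum(.data$intensity), .groups = "drop")
  grid |>
    dplyr::left_join(obs, by = c(grid_cols, "sample_id")) |>
    dplyr::mutate(intensity = dplyr::coalesce(.data$intensity, 0)) |>
    dplyr::arrange(.data$species, .data$time_h,
                   if (has_subject) .data$subject else NULL)
}
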