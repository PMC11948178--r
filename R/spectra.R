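#' Read an intact LC-MS run
#'
#' Accepts standard mzML (via the mzR backend) or a plain CSV spectrum
#' dialect with columns `rt` (minutes), `mz`, `intensity`, one row per
#' point, scans identified by distinct `rt` values.
#'
#' @param path file path ending in `.mzML`/`.mzml` or `.csv`.
#' @return a run: tibble with one row per scan, columns `scan`, `rt`
#'   (minutes), `mode` (`"profile"`/`"centroid"`), and `peaks`, a list
#'   column of `tibble(mz, intensity)` sorted by m/z; scans sorted by rt.
#' @export
read_run <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (grepl("\\.mzml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("mzR", quietly = TRUE)) {
      abort("reading mzML requires the mzR package")
    }
    fh <- mzR::openMSfile(path)
    on.exit(mzR::close(fh), add = TRUE)
    hd <- mzR::header(fh)
    if (!nrow(hd)) abort("empty run: no spectra in file")
    pk <- mzR::peaks(fh)
    if (is.matrix(pk)) pk <- list(pk)
    run <- tibble::tibble(
      rt = hd$retentionTime / 60,
      mode = ifelse(isTRUE(hd$centroided) | hd$centroided %in% TRUE,
                    "centroid", "profile"),
      peaks = lapply(pk, function(m) {
        tibble::tibble(mz = m[, 1], intensity = m[, 2]) |> dplyr::arrange(.data$mz)
      })
    )
  } else {
    x <- readr::read_csv(path, show_col_types = FALSE)
    need <- c("rt", "mz", "intensity")
    if (!all(need %in% names(x))) {
      abort("CSV spectrum dialect needs columns rt, mz, intensity")
    }
    if (!nrow(x)) abort("empty run: no spectra in file")
    run <- x[, need] |>
      dplyr::arrange(.data$rt, .data$mz) |>
      tidyr::nest(peaks = dplyr::all_of(c("mz", "intensity"))) |>
      dplyr::mutate(mode = "profile")
  }
  run <- run |> dplyr::arrange(.data$rt) |>
    dplyr::mutate(scan = dplyr::row_number()) |>
    dplyr::select("scan", "rt", "mode", "peaks")
  for (p in run$peaks) {
    if (is.unsorted(p$mz, strictly = TRUE)) abort("m/z values must be strictly increasing")
    if (any(p$intensity < 0)) abort("negative intensities in spectrum")
  }
  run
}

#' Write a run in the CSV spectrum dialect
#' @param run run tibble (see [read_run()]).
#' @param path output CSV path.
#' @export
write_run_csv <- function(run, path) {
  long <- run |>
    dplyr::select("rt", "peaks") |>
    tidyr::unnest("peaks")
  readr::write_csv(long, path)
  invisible(path)
}

#' Write a run to mzML
#'
#' Uses the mzR/proteowizard backend; MS1 profile scans.
#'
#' @param run run tibble.
#' @param path output `.mzML` path.
#' @export
write_run_mzml <- function(run, path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    abort("writing mzML requires the mzR package")
  }
  n <- nrow(run)
  pk <- lapply(run$peaks, function(p) cbind(mz = p$mz, intensity = p$intensity))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 1L,
    peaksCount = vapply(pk, nrow, integer(1)),
    totIonCurrent = vapply(run$peaks, function(p) sum(p$intensity), numeric(1)),
    retentionTime = run$rt * 60,
    basePeakMZ = vapply(run$peaks, function(p)
      if (nrow(p)) p$mz[which.max(p$intensity)] else 0, numeric(1)),
    basePeakIntensity = vapply(run$peaks, function(p)
      if (nrow(p)) max(p$intensity) else 0, numeric(1)),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(run$peaks, function(p) if (nrow(p)) min(p$mz) else 0, numeric(1)),
    highMZ = vapply(run$peaks, function(p) if (nrow(p)) max(p$mz) else 0, numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)),
    centroided = run$mode == "centroid",
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_, scanWindowLowerLimit = NA_real_,
    scanWindowUpperLimit = NA_real_
  )
  mzR::writeMSData(pk, file = path, header = hdr)
  invisible(path)
}

#' Sum scans inside a retention-time window into a composite spectrum
#'
#' Scans are interpolated onto a common m/z grid (that of the densest scan
#' in the window) and intensity-summed; used to pool an elution region
#' (e.g. the light-chain window) before deconvolution.
#'
#' @param run run tibble from [read_run()] or the simulator.
#' @param start,end window bounds in minutes (inclusive).
#' @return `tibble(mz, intensity)` composite spectrum.
#' @export
sum_window <- function(run, start, end) {
  stopifnot(start < end)
  sel <- run$peaks[run$rt >= start & run$rt <= end]
  if (!length(sel)) {
    abort(paste0("no scans in retention-time window [", start, ", ", end, "] min"))
  }
  grid <- sel[[which.max(vapply(sel, nrow, integer(1)))]]$mz
  total <- numeric(length(grid))
  for (p in sel) {
    y <- approx(p$mz, p$intensity, xout = grid, rule = 1)$y
    y[is.na(y)] <- 0
    total <- total + y
  }
  tibble::tibble(mz = grid, intensity = total)
}

# Piecewise baseline: minimum per m/z bin of the given width, linearly
# interpolated back onto the full grid.
binned_min_baseline <- function(mz, intensity, window) {
  bins <- floor((mz - mz[1]) / window)
  idx <- split(seq_along(mz), bins)
  bx <- vapply(idx, function(ii) mean(mz[ii]), numeric(1))
  bm <- vapply(idx, function(ii) min(intensity[ii]), numeric(1))
  if (length(bx) == 1L) return(rep(bm, length(mz)))
  approx(bx, bm, xout = mz, rule = 2)$y
}

#' Baseline subtraction and noise removal for a profile spectrum
#'
#' Smooths with a short moving average matched to the profile peak width
#' (noise shrinks by about the square root of the window while peak areas
#' are conserved), subtracts a binned-minimum baseline (bin width
#' `baseline_window` in m/z units, linearly interpolated), zeroes
#' intensities below a noise floor of `noise_k` times the median absolute
#' deviation of the residual, and removes isolated speckle: surviving runs
#' shorter than `min_run` grid points are zeroed, since a genuine profile
#' peak spans several points.
#'
#' @param spectrum `tibble(mz, intensity)`.
#' @param baseline_window baseline bin width in m/z units; must be much
#'   wider than a peak.
#' @param noise_k noise-floor multiplier (default 5).
#' @param min_run minimum length (grid points) of a surviving intensity
#'   run; shorter runs are treated as noise spikes.
#' @param smooth_points odd moving-average window in grid points (1
#'   disables smoothing).
#' @return preprocessed `tibble(mz, intensity)`, non-negative.
#' @export
preprocess <- function(spectrum, baseline_window = 20, noise_k = 5,
                       min_run = 3L, smooth_points = 5L) {
  if (!nrow(spectrum)) return(spectrum)
  y0 <- spectrum$intensity
  if (smooth_points > 1L && nrow(spectrum) > smooth_points) {
    kern <- rep(1 / smooth_points, smooth_points)
    y0 <- as.numeric(stats::filter(y0, kern, sides = 2))
    half <- (smooth_points - 1L) %/% 2L
    y0[seq_len(half)] <- spectrum$intensity[seq_len(half)]
    nn <- length(y0)
    y0[(nn - half + 1L):nn] <- spectrum$intensity[(nn - half + 1L):nn]
  }
  base <- binned_min_baseline(spectrum$mz, y0, baseline_window)
  resid <- y0 - base
  # the binned-minimum baseline sits below the noise band, so the residual
  # is positive-shifted; re-centre at the median before estimating noise
  resid <- resid - median(resid)
  noise <- mad(resid)
  floor_ <- noise_k * noise
  y <- pmax(resid, 0)
  y[y < floor_] <- 0
  if (min_run > 1L && any(y > 0)) {
    r <- rle(y > 0)
    short <- r$values & r$lengths < min_run
    if (any(short)) {
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(short)) y[starts[k]:ends[k]] <- 0
    }
  }
  tibble::tibble(mz = spectrum$mz, intensity = y)
}

#' Preprocess every scan of a run
#'
#' Applies [preprocess()] per scan. Cleaning scans before window summation
#' preserves weak species better than cleaning the composite: summing n
#' scans grows the noise floor by sqrt(n) while an eluting species'
#' signal is concentrated in a few scans.
#'
#' @inheritParams preprocess
#' @param run run tibble from [read_run()] or the simulator.
#' @return the run with cleaned scan spectra.
#' @export
preprocess_run <- function(run, baseline_window = 20, noise_k = 5,
                           min_run = 3L, smooth_points = 5L) {
  run$peaks <- lapply(run$peaks, preprocess, baseline_window = baseline_window,
                      noise_k = noise_k, min_run = min_run,
                      smooth_points = smooth_points)
  run
}
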