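#' Deconvolution configuration
#'
#' Defaults follow common intact-antibody settings: charges 10-60,
#' 1000-5000 m/z, neutral masses 20-80 kDa on a 0.5 Da grid, at least
#' 3 supporting charge states.
#'
#' @param charge_range integer range of charge states considered.
#' @param mz_range m/z window used for scoring.
#' @param mass_range neutral-mass search window in Da.
#' @param grid_step neutral-mass grid step in Da.
#' @param min_charges minimum number of charge states that must carry
#'   signal for a mass to be reported.
#' @param support_frac a charge state "supports" a mass when its
#'   interpolated intensity exceeds this fraction of the spectrum maximum.
#' @param peak_floor_frac score local maxima below this fraction of the
#'   top score are ignored.
#' @param min_charge_fill minimum fraction of charge states supported
#'   within a candidate's own supporting charge span; a harmonic at 2M or
#'   M/2 only collects every other charge state (fill near 0.5), so this
#'   filter rejects harmonics regardless of their score.
#' @param harmonic_factor a peak is dropped when another peak has at least
#'   this score ratio over it and shares at least `harmonic_overlap` of its
#'   supporting m/z positions. Harmonic artifacts (half/double mass and
#'   other rational multiples) ride on a subset of the true peak's charge
#'   lines, so their support is fully shared and their score is at most
#'   about half the true score; the default 1.5 sits between that ratio
#'   and 1. Genuinely distinct masses share no support points.
#' @param harmonic_overlap shared-support fraction for the dominance rule.
#' @param support_mz_tol m/z distance below which two supporting positions
#'   count as the same line (about one profile peak width).
#' @param min_separation minimum neutral-mass distance (Da) between
#'   reported peaks; within it only the strongest is kept.
#' @return list of settings for [deconvolve()].
#' @export
deconv_config <- function(charge_range = c(10L, 60L),
                          mz_range = c(1000, 5000),
                          mass_range = c(20000, 80000),
                          grid_step = 0.5,
                          min_charges = 3L,
                          support_frac = 0.02,
                          peak_floor_frac = 0.01,
                          min_charge_fill = 0.6,
                          harmonic_factor = 1.5,
                          harmonic_overlap = 0.5,
                          support_mz_tol = 0.25,
                          min_separation = 5) {
  list(charge_range = charge_range, mz_range = mz_range,
       mass_range = mass_range, grid_step = grid_step,
       min_charges = as.integer(min_charges), support_frac = support_frac,
       peak_floor_frac = peak_floor_frac, min_charge_fill = min_charge_fill,
       harmonic_factor = harmonic_factor, harmonic_overlap = harmonic_overlap,
       support_mz_tol = support_mz_tol, min_separation = min_separation)
}

#' Deconvolute a multiply charged spectrum to neutral masses
#'
#' Charge-envelope summation: for every candidate neutral mass M on a
#' grid, the score is the summed interpolated intensity at
#' `(M + z * 1.00727646) / z` over the configured charge states (restricted
#' to the m/z window). Local maxima of the score above threshold become
#' mass peaks, refined by parabolic interpolation. Harmonic artifacts at
#' 2M and M/2 are removed by a charge-fill filter plus a dominance rule
#' (see [deconv_config()]). Isotope structure is not modelled: at 20-80 kDa
#' the envelopes are isotopically unresolved and reported masses live on
#' the average-mass scale.
#'
#' @param spectrum `tibble(mz, intensity)` (typically from [sum_window()]
#'   and [preprocess()]).
#' @param config list from [deconv_config()].
#' @return tibble of class `adc_peaks`: `neutral_mass` (Da), `intensity`
#'   (summed envelope score), `n_charges_supporting`, `charge_fill`,
#'   sorted by decreasing intensity. Zero rows when the spectrum is empty.
#' @export
deconvolve <- function(spectrum, config = deconv_config()) {
  cfg <- config
  sel <- spectrum$mz >= cfg$mz_range[1] & spectrum$mz <= cfg$mz_range[2]
  mz <- spectrum$mz[sel]
  y <- spectrum$intensity[sel]
  empty <- tibble::tibble(neutral_mass = double(), intensity = double(),
                          n_charges_supporting = integer(),
                          charge_fill = double())
  class(empty) <- c("adc_peaks", class(empty))
  if (length(mz) < 2L || all(y == 0)) return(empty)
  masses <- seq(cfg$mass_range[1], cfg$mass_range[2], by = cfg$grid_step)
  zs <- seq(cfg$charge_range[1], cfg$charge_range[2])
  sup_floor <- cfg$support_frac * max(y)
  score <- numeric(length(masses))
  nsup <- integer(length(masses))
  zmin <- rep(Inf, length(masses))
  zmax <- rep(-Inf, length(masses))
  for (z in zs) {
    xout <- (masses + z * PROTON_MASS) / z
    inside <- xout >= cfg$mz_range[1] & xout <= cfg$mz_range[2]
    yi <- numeric(length(masses))
    if (any(inside)) {
      v <- approx(mz, y, xout = xout[inside], rule = 1)$y
      v[is.na(v)] <- 0
      yi[inside] <- v
    }
    score <- score + yi
    sup <- yi > sup_floor
    nsup <- nsup + sup
    zmin[sup] <- pmin(zmin[sup], z)
    zmax[sup] <- pmax(zmax[sup], z)
  }
  floor_ <- cfg$peak_floor_frac * max(score)
  n <- length(masses)
  is_max <- c(FALSE, score[2:(n - 1)] >= score[1:(n - 2)] &
                     score[2:(n - 1)] > score[3:n], FALSE)
  cand <- which(is_max & score > floor_ & nsup >= cfg$min_charges)
  if (!length(cand)) return(empty)
  fill <- nsup[cand] / (zmax[cand] - zmin[cand] + 1)
  keep <- fill >= cfg$min_charge_fill
  cand <- cand[keep]
  fill <- fill[keep]
  if (!length(cand)) return(empty)
  # apex refinement: least-squares parabola on log score over the hump's
  # upper part (exact for a Gaussian apex, averages grid noise); the hump
  # width scales with charge, so size the window by the observed half-width
  refined <- vapply(cand, function(i) {
    w <- 2L
    while (w < 12L && i - w > 1L && i + w < n &&
           score[i - w] > 0.6 * score[i] && score[i + w] > 0.6 * score[i]) {
      w <- w + 1L
    }
    lo <- max(1L, i - w); hi <- min(n, i + w)
    idx <- lo:hi
    ok <- score[idx] > 0
    if (sum(ok) < 3L) return(masses[i])
    x <- masses[idx][ok] - masses[i]
    yl <- log(score[idx][ok])
    fit <- stats::lm.fit(cbind(1, x, x^2), yl)
    a2 <- fit$coefficients[3]; a1 <- fit$coefficients[2]
    if (!is.finite(a2) || a2 >= 0) {
      a <- score[max(i - 1L, 1L)]; b <- score[i]; c2 <- score[min(i + 1L, n)]
      den <- a - 2 * b + c2
      if (den >= 0) return(masses[i])
      return(masses[i] + 0.5 * (a - c2) / den * cfg$grid_step)
    }
    apex <- -a1 / (2 * a2)
    if (abs(apex) > w * cfg$grid_step) return(masses[i])
    masses[i] + apex
  }, numeric(1))
  # final mass: per-charge line-apex averaging -- locate each supporting
  # charge line's apex on the m/z grid (3-point parabola), convert to a
  # neutral mass, and intensity-weight; the score hump is charge-summed and
  # slightly skewed, individual line apexes are not
  refined <- vapply(refined, function(M0) {
    mz_step <- median(diff(mz))
    est <- c(); wt <- c()
    for (z in zs) {
      x0 <- (M0 + z * PROTON_MASS) / z
      if (x0 < mz[1] || x0 > mz[length(mz)]) next
      i0 <- which.min(abs(mz - x0))
      win <- max(1L, i0 - round(0.3 / mz_step)):min(length(mz), i0 + round(0.3 / mz_step))
      ia <- win[which.max(y[win])]
      if (y[ia] <= sup_floor || ia <= 1L || ia >= length(mz)) next
      a <- y[ia - 1]; b <- y[ia]; c2 <- y[ia + 1]
      den <- a - 2 * b + c2
      apex_mz <- if (den < 0) mz[ia] + 0.5 * (a - c2) / den * mz_step else mz[ia]
      est <- c(est, z * (apex_mz - PROTON_MASS))
      wt <- c(wt, y[ia])
    }
    if (length(est) < 2L) return(M0)
    # a line apex can be captured by another species' nearby charge line;
    # trim estimates far from the median before weighting
    ok <- abs(est - stats::median(est)) <= 4 * cfg$grid_step
    if (sum(ok) >= 2L) sum(est[ok] * wt[ok]) / sum(wt[ok]) else M0
  }, numeric(1))
  pk <- tibble::tibble(
    neutral_mass = refined,
    intensity = score[cand],
    n_charges_supporting = nsup[cand],
    charge_fill = fill
  )
  pk <- pk[order(-pk$intensity), ]
  if (nrow(pk) > 1L) {  # keep only the strongest peak within min_separation
    keep_sep <- rep(TRUE, nrow(pk))
    for (i in 2:nrow(pk)) {
      if (any(keep_sep[1:(i - 1)] &
              abs(pk$neutral_mass[1:(i - 1)] - pk$neutral_mass[i]) <
                cfg$min_separation)) {
        keep_sep[i] <- FALSE
      }
    }
    pk <- pk[keep_sep, ]
  }
  pk <- drop_harmonics(pk, mz, y, cfg, sup_floor)
  pk <- pk[pk$neutral_mass >= cfg$mass_range[1] &
           pk$neutral_mass <= cfg$mass_range[2], ]
  class(pk) <- c("adc_peaks", class(pk))
  pk
}

support_points <- function(M, mz, y, cfg, sup_floor) {
  zs <- seq(cfg$charge_range[1], cfg$charge_range[2])
  xout <- (M + zs * PROTON_MASS) / zs
  ok <- xout >= cfg$mz_range[1] & xout <= cfg$mz_range[2]
  v <- rep(0, length(zs))
  if (any(ok)) {
    vv <- approx(mz, y, xout = xout[ok], rule = 1)$y
    vv[is.na(vv)] <- 0
    v[ok] <- vv
  }
  sel <- v > sup_floor
  list(x = xout[sel], v = v[sel])
}

drop_harmonics <- function(pk, mz, y, cfg, sup_floor) {
  if (nrow(pk) < 2L) return(pk)
  sp <- lapply(pk$neutral_mass, support_points, mz = mz, y = y,
               cfg = cfg, sup_floor = sup_floor)
  drop <- logical(nrow(pk))
  # double-mass artifacts score as high as their parent (they sample the
  # same line apexes at even charges), so dominance cannot reject them;
  # instead test whether the high-mass peak has any support of its own
  # beyond the parent's charge lines (a genuine species has odd-charge
  # lines the half-mass peak cannot explain)
  zs_all <- seq(cfg$charge_range[1], cfg$charge_range[2])
  for (i in seq_len(nrow(pk))) {
    for (j in seq_len(nrow(pk))) {
      if (i == j || drop[i] || drop[j]) next
      if (abs(pk$neutral_mass[j] - 2 * pk$neutral_mass[i]) < 3 &&
          length(sp[[j]]$x)) {
        parent_lines <- (pk$neutral_mass[i] + zs_all * PROTON_MASS) / zs_all
        explained <- vapply(sp[[j]]$x, function(x) {
          any(abs(parent_lines - x) < cfg$support_mz_tol)
        }, logical(1))
        own <- sum(sp[[j]]$v[!explained]) / sum(sp[[j]]$v)
        if (own < 0.3) drop[j] <- TRUE
      }
    }
  }
  # weakest first, against the union of all sufficiently stronger survivors:
  # harmonic and composite artifacts borrow their lines from true peaks
  for (i in order(pk$intensity)) {
    if (drop[i]) next
    if (!length(sp[[i]]$x)) next
    stronger <- which(!drop &
                      pk$intensity >= cfg$harmonic_factor * pk$intensity[i])
    stronger <- setdiff(stronger, i)
    if (!length(stronger)) next
    xs <- unlist(lapply(sp[stronger], `[[`, "x"))
    is_shared <- vapply(sp[[i]]$x, function(x) {
      any(abs(xs - x) < cfg$support_mz_tol)
    }, logical(1))
    shared <- sum(sp[[i]]$v[is_shared]) / sum(sp[[i]]$v)
    if (shared >= cfg$harmonic_overlap) drop[i] <- TRUE
  }
  pk[!drop, ]
}
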