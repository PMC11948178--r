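#' Define a simulation scenario
#'
#' Ground-truth conditions for the synthetic study: antibody-like chains,
#' a conjugate mass, per-site biotransformation kinetics, PK time points,
#' subjects and the noise model. Defaults emulate the study design the
#' package targets: a DAR8 cysteine conjugate (LC 1 site, HC 3 sites),
#' plasma sampling at 1-336 h with near-complete thiosuccinimide
#' hydrolysis by 120 h (first-order per-site rate 0.04 /h), minor
#' deconjugation-then-cysteinylation (0.002 /h), and n = 3 subjects.
#'
#' @param chains tibble with `chain_id`, `sequence`, `n_sites`,
#'   `n_disulfides`, `glycan`, `rt_center`, `rt_sigma` (minutes),
#'   `mass_range_lo`, `mass_range_hi` (deconvolution window per chain);
#'   default: synthetic LC/HC from [make_synthetic_chains()].
#' @param conjugate_formula elemental formula of the intact linker-payload
#'   addition; default: the bundled synthetic PBD-style structure.
#' @param k_hyd per-payload thiosuccinimide hydrolysis rate, per hour.
#' @param k_deconj per-payload deconjugation (then cysteinylation) rate.
#' @param time_h PK time points in hours.
#' @param n_subjects biological replicates.
#' @param abundance_cv multiplicative (lognormal) CV on species
#'   intensities per subject.
#' @param snr spectral signal-to-noise (max signal over noise sd).
#' @param resolution mass-spectral resolving power (FWHM definition).
#' @param z_sigma width of the Gaussian charge envelope (charge units).
#' @param target_mz m/z at which charge envelopes are centred.
#' @param mz_range,mz_step simulated m/z grid.
#' @param rt_range,rt_step simulated retention-time grid (minutes).
#' @param baseline flat baseline level relative to max signal.
#' @param chain_intensity total signal per chain (arbitrary units).
#' @return list of class `sim_scenario`.
#' @export
sim_scenario <- function(chains = make_synthetic_chains(),
                         conjugate_formula = NULL,
                         k_hyd = 0.04, k_deconj = 0.002,
                         time_h = c(1, 24, 72, 120, 168, 336),
                         n_subjects = 3,
                         abundance_cv = 0.1,
                         snr = 50,
                         resolution = 8000,
                         z_sigma = 2,
                         target_mz = 1800,
                         mz_range = c(1000, 5000), mz_step = 0.05,
                         rt_range = c(1.5, 5.3), rt_step = 0.1,
                         baseline = 0.02,
                         chain_intensity = c(LC = 1e6, HC = 1e6)) {
  if (is.null(conjugate_formula)) {
    g <- parse_structure(synthetic_pbd_linker_payload(),
                         attachment = maleimide_pattern())
    conjugate_formula <- formula_string(mol_formula(g))
  }
  stopifnot(k_hyd >= 0, k_deconj >= 0, all(time_h >= 0))
  structure(list(
    chains = chains, conjugate_formula = conjugate_formula,
    conjugate_mono = formula_mass(conjugate_formula, "monoisotopic"),
    conjugate_avg = formula_mass(conjugate_formula, "average"),
    k_hyd = k_hyd, k_deconj = k_deconj, time_h = time_h,
    n_subjects = n_subjects, abundance_cv = abundance_cv, snr = snr,
    resolution = resolution, z_sigma = z_sigma, target_mz = target_mz,
    mz_range = mz_range, mz_step = mz_step,
    rt_range = rt_range, rt_step = rt_step, baseline = baseline,
    chain_intensity = chain_intensity
  ), class = "sim_scenario")
}

#' Synthetic antibody-like chains
#'
#' Deterministic random amino-acid sequences with intact-antibody-like
#' masses (LC about 23 kDa, HC about 49 kDa) and the DAR8
#' cysteine-conjugate site convention (LC 1, HC 3); these are synthetic
#' stand-ins, not real antibody sequences.
#'
#' @param seed RNG seed for the sequence draw.
#' @return chains tibble for [sim_scenario()].
#' @export
make_synthetic_chains <- function(seed = 20251L) {
  aa <- c("G","A","S","P","V","T","C","L","I","N",
          "D","Q","K","E","M","H","F","R","Y","W")
  wt <- c(7, 8, 7, 5, 7, 6, 2, 9, 5, 4, 5, 4, 6, 6, 2, 2, 4, 5, 3, 1)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  mk <- function(n) paste(sample(aa, n, replace = TRUE, prob = wt), collapse = "")
  tibble::tibble(
    chain_id = c("LC", "HC"),
    sequence = c(mk(212), mk(446)),
    n_sites = c(1L, 3L),
    n_disulfides = c(2L, 4L),
    glycan = c("none", "G0F"),
    rt_center = c(1.95, 4.5),
    rt_sigma = c(0.08, 0.1),
    mass_range_lo = c(20000, 40000),
    mass_range_hi = c(40000, 80000)
  )
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Ground-truth species fractions under first-order site kinetics
#'
#' Each conjugation site evolves independently: an unhydrolysed payload
#' hydrolyses at rate `k_hyd` or deconjugates (the freed thiol is then
#' cysteinylated) at rate `k_deconj`, both first order; hydrolysis
#' protects against deconjugation. The chain species distribution is the
#' multinomial over sites of the three per-site states.
#'
#' @param n_sites conjugation sites on the chain.
#' @param t time in hours.
#' @param k_hyd,k_deconj rates per hour.
#' @return tibble with `dar` (payloads retained), `n_hyd` (hydrolysed
#'   payloads), `caps` (cysteinylated sites) and `fraction`, summing to 1.
#' @export
#' @examples
#' simulate_species(2, t = log(2) / 0.04, k_hyd = 0.04)  # p = 0.5 binomial
simulate_species <- function(n_sites, t, k_hyd, k_deconj = 0) {
  stopifnot(t >= 0, k_hyd >= 0, k_deconj >= 0)
  ktot <- k_hyd + k_deconj
  p_u <- exp(-ktot * t)
  done <- 1 - p_u
  p_h <- if (ktot > 0) k_hyd / ktot * done else 0
  p_c <- if (ktot > 0) k_deconj / ktot * done else 0
  combos <- expand.grid(n_unhyd = 0:n_sites, n_hyd = 0:n_sites, caps = 0:n_sites)
  combos <- combos[rowSums(combos) == n_sites, ]
  frac <- apply(combos, 1, function(r) {
    factorial(n_sites) / (factorial(r[1]) * factorial(r[2]) * factorial(r[3])) *
      p_u^r[1] * p_h^r[2] * p_c^r[3]
  })
  out <- tibble::tibble(
    dar = as.integer(combos$n_unhyd + combos$n_hyd),
    n_hyd = as.integer(combos$n_hyd),
    caps = as.integer(combos$caps),
    fraction = as.numeric(frac)
  )
  out[order(-out$fraction), ]
}

species_label <- function(chain_id, dar, n_hyd, caps, glycan) {
  paste(c(chain_id,
          if (dar > 0) paste0(dar, "PL"),
          if (caps > 0) paste0(caps, "Cys"),
          if (n_hyd > 0) paste0(n_hyd, "H2O"),
          if (glycan != "none") glycan), collapse = " + ")
}

# Theoretical mass of one simulated species on the average scale (the scale
# unresolved intact deconvolution reports).
species_mass <- function(chain, scen, dar, n_hyd, caps, mode = "average") {
  chain_mass(chain$sequence, chain$n_disulfides, mode) +
    apply_fixed_mods(chain$sequence, mode = mode) +
    glycan_mass(chain$glycan, mode) +
    dar * (if (mode == "average") scen$conjugate_avg else scen$conjugate_mono) +
    n_hyd * formula_mass("H2O", mode) +
    caps * formula_mass(CYSTEINYL_FORMULA, mode)
}

#' Simulate one electrospray spectrum of a proteoform mixture
#'
#' Each species gets a Gaussian charge envelope (centred where its m/z is
#' nearest `target_mz`, width `z_sigma`) of Gaussian profile peaks whose
#' width follows the configured resolving power, plus a flat baseline and
#' additive Gaussian noise scaled by `snr`. Deterministic given `seed`.
#'
#' @param masses neutral species masses in Da.
#' @param abundances relative species abundances (>= 0).
#' @param scenario a [sim_scenario()] (noise/grid settings are read from
#'   it).
#' @param seed RNG seed; identical seeds give identical spectra.
#' @return `tibble(mz, intensity)` profile spectrum.
#' @export
simulate_spectrum <- function(masses, abundances, scenario = sim_scenario(),
                              seed = 1L) {
  scen <- scenario
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  grid <- seq(scen$mz_range[1], scen$mz_range[2], by = scen$mz_step)
  signal <- signal_on_grid(grid, masses, abundances, scen)
  peak_max <- max(signal, 1e-12)
  noise_sd <- peak_max / scen$snr
  y <- signal + scen$baseline * peak_max +
    rnorm(length(grid), sd = noise_sd)
  tibble::tibble(mz = grid, intensity = pmax(y, 0))
}

signal_on_grid <- function(grid, masses, abundances, scen) {
  signal <- numeric(length(grid))
  zs <- 1:80
  for (si in seq_along(masses)) {
    if (abundances[si] <= 0) next
    M <- masses[si]
    z0 <- M / (scen$target_mz - PROTON_MASS)
    w <- dnorm(zs, mean = z0, sd = scen$z_sigma)
    w <- w / sum(w)
    use <- which(w > 0.005)
    for (z in use) {
      center <- (M + z * PROTON_MASS) / z
      if (center < grid[1] || center > grid[length(grid)]) next
      sigma <- center / scen$resolution / 2.3548
      lo <- findInterval(center - 5 * sigma, grid)
      hi <- findInterval(center + 5 * sigma, grid)
      if (hi <= lo) next
      idx <- lo:hi
      signal[idx] <- signal[idx] +
        abundances[si] * w[z] * dnorm(grid[idx], center, sigma) * sigma * 2.5066
    }
  }
  signal
}

#' Simulate one LC-MS run for a subject and time point
#'
#' Computes ground-truth species fractions from the kinetic model,
#' applies subject-level multiplicative (lognormal) abundance noise, and
#' renders profile scans over the retention-time grid with Gaussian
#' elution profiles per chain.
#'
#' @param scenario a [sim_scenario()].
#' @param subject subject index (enters the seed).
#' @param time_h time point in hours.
#' @param seed base RNG seed for this run.
#' @return list with `run` (scan tibble as from [read_run()]), `truth`
#'   (tibble: `chain_id`, `species`, `mass`, `fraction`, `intensity`) and
#'   `windows` (tibble: `chain_id`, `start`, `end`, `mass_range_lo`,
#'   `mass_range_hi`).
#' @export
simulate_run <- function(scenario, subject = 1L, time_h = 24, seed = 1L) {
  scen <- scenario
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed + 7919L * subject)
  truth <- list()
  for (ci in seq_len(nrow(scen$chains))) {
    ch <- scen$chains[ci, ]
    sp <- simulate_species(ch$n_sites, time_h, scen$k_hyd, scen$k_deconj)
    sp <- sp[sp$fraction > 0.01, ]  # below ~1% is under the detection floor
    inten <- scen$chain_intensity[[ch$chain_id]] * sp$fraction *
      exp(rnorm(nrow(sp), 0, scen$abundance_cv))
    truth[[ci]] <- tibble::tibble(
      chain_id = ch$chain_id,
      species = mapply(species_label, ch$chain_id, sp$dar, sp$n_hyd, sp$caps,
                       ch$glycan),
      dar = sp$dar, n_hyd = sp$n_hyd, caps = sp$caps,
      mass = mapply(function(d, h, cc) species_mass(ch, scen, d, h, cc),
                    sp$dar, sp$n_hyd, sp$caps),
      fraction = sp$fraction,
      intensity = inten,
      rt_center = ch$rt_center, rt_sigma = ch$rt_sigma
    )
  }
  truth <- dplyr::bind_rows(truth)
  grid <- seq(scen$mz_range[1], scen$mz_range[2], by = scen$mz_step)
  rts <- seq(scen$rt_range[1], scen$rt_range[2], by = scen$rt_step)
  peak_ref <- NULL
  scans <- vector("list", length(rts))
  for (k in seq_along(rts)) {
    prof <- dnorm(rts[k], truth$rt_center, truth$rt_sigma) *
      truth$rt_sigma * 2.5066  # unit apex height per species
    ab <- truth$intensity * prof
    signal <- signal_on_grid(grid, truth$mass, ab, scen)
    if (is.null(peak_ref)) {
      peak_ref <- max(signal_on_grid(grid, truth$mass, truth$intensity, scen))
    }
    noise_sd <- peak_ref / scen$snr
    y <- signal + scen$baseline * peak_ref + rnorm(length(grid), sd = noise_sd)
    scans[[k]] <- tibble::tibble(mz = grid, intensity = pmax(y, 0))
  }
  run <- tibble::tibble(scan = seq_along(rts), rt = rts, mode = "profile",
                        peaks = scans)
  windows <- scen$chains |>
    dplyr::transmute(.data$chain_id,
                     start = .data$rt_center - 3 * .data$rt_sigma,
                     end = .data$rt_center + 3 * .data$rt_sigma,
                     mass_range_lo = .data$mass_range_lo,
                     mass_range_hi = .data$mass_range_hi)
  list(run = run, truth = truth, windows = windows)
}

#' Random toy linker-payload structures
#'
#' A random tree of C/N/O atoms with valences respected, optionally with a
#' grafted five-membered ring; atom 1 is the attachment site. Used as
#' oracle fixtures for the cleavage enumerator.
#'
#' @param n_linker_atoms heavy atoms in the acyclic part (3..12).
#' @param seed RNG seed.
#' @param with_ring graft a cyclopentane ring on a random atom.
#' @return MOL V2000 text.
#' @export
make_toy_linker_payload <- function(n_linker_atoms, seed = 1L,
                                    with_ring = FALSE) {
  stopifnot(n_linker_atoms >= 3, n_linker_atoms <= 12)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  val <- c(C = 4L, N = 3L, O = 2L)
  elements <- "C"
  free <- c(4L)
  bonds <- list()
  for (a in 2:n_linker_atoms) {
    el <- sample(names(val), 1, prob = c(0.7, 0.15, 0.15))
    open <- which(free > 0)
    parent <- if (length(open) == 1L) open else sample(open, 1)
    elements <- c(elements, el)
    free[parent] <- free[parent] - 1L
    free <- c(free, val[[el]] - 1L)
    bonds[[length(bonds) + 1L]] <- c(parent, a, 1L)
  }
  if (with_ring) {
    open <- which(free > 0)
    host <- if (length(open) == 1L) open else sample(open, 1)
    n0 <- length(elements)
    elements <- c(elements, rep("C", 5))
    ring <- n0 + 1:5
    bonds[[length(bonds) + 1L]] <- c(host, ring[1], 1L)
    for (k in 1:4) bonds[[length(bonds) + 1L]] <- c(ring[k], ring[k + 1], 1L)
    bonds[[length(bonds) + 1L]] <- c(ring[5], ring[1], 1L)
  }
  bm <- do.call(rbind, bonds)
  write_mol_text("toy linker-payload", elements, bm)
}

write_mol_text <- function(title, elements, bond_matrix) {
  n <- length(elements)
  b <- nrow(bond_matrix)
  header <- c(title, "  adcbiotx", "",
              sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, b))
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   seq_len(n) * 0.1, 0, 0, elements)
  bondl <- sprintf("%3d%3d%3d  0  0  0  0",
                   bond_matrix[, 1], bond_matrix[, 2], bond_matrix[, 3])
  paste(c(header, atoms, bondl, "M  END"), collapse = "\n")
}

#' Synthetic PBD-dimer-style linker-payload structure
#'
#' A maleimide-capped dipeptide linker carrying an aromatic payload head,
#' in the style of pyrrolobenzodiazepine linker-payloads. This is a
#' synthetic stand-in (the real structure of such payloads is typically
#' proprietary), shaped so that the constrained cleavage enumeration
#' (up to 2 bonds, no ring bonds, attachment-filtered) yields 46 products
#' -- the combinatorial size reported for this class of workflow. Also
#' shipped as `inst/extdata/sg3584_like_synthetic.mol`.
#'
#' @return MOL V2000 text.
#' @export
synthetic_pbd_linker_payload <- function() {
  path <- system.file("extdata", "sg3584_like_synthetic.mol",
                      package = "adcbiotx")
  if (nzchar(path)) return(paste(readLines(path), collapse = "\n"))
  abort("bundled structure file not found")
}
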