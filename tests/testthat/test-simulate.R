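test_that("site kinetics give the multinomial species distribution", {
  # t = 0: everything intact and unhydrolysed
  sp0 <- simulate_species(3, t = 0, k_hyd = 0.04, k_deconj = 0.002)
  expect_equal(sp0$fraction[sp0$dar == 3 & sp0$n_hyd == 0], 1)
  expect_equal(sum(sp0$fraction), 1)
  # k*t -> large: complete hydrolysis
  spI <- simulate_species(3, t = 1e5, k_hyd = 0.04)
  expect_equal(spI$fraction[spI$n_hyd == 3], 1, tolerance = 1e-9)
  # half-hydrolysis on two sites: the 1/4, 1/2, 1/4 binomial
  t_half <- log(2) / 0.04
  sp <- simulate_species(2, t = t_half, k_hyd = 0.04)
  f <- sp$fraction[match(0:2, sp$n_hyd)]
  expect_equal(f, c(0.25, 0.5, 0.25), tolerance = 1e-12)
  expect_equal(sum(sp$fraction), 1, tolerance = 1e-12)
})

test_that("expected hydrolysis is non-decreasing in time", {
  for (s in 1:3) {
    h <- vapply(c(0, 1, 6, 24, 72, 120, 336), function(t) {
      sp <- simulate_species(s, t, k_hyd = 0.04, k_deconj = 0.002)
      sum(sp$n_hyd * sp$fraction) / s
    }, numeric(1))
    expect_false(is.unsorted(h))
  }
})

test_that("simulated spectra are deterministic given the seed", {
  scen <- sim_scenario(snr = 30)
  a <- simulate_spectrum(c(25000, 50000), c(1, 0.5), scen, seed = 9)
  b <- simulate_spectrum(c(25000, 50000), c(1, 0.5), scen, seed = 9)
  expect_identical(a, b)
  c2 <- simulate_spectrum(c(25000, 50000), c(1, 0.5), scen, seed = 10)
  expect_false(identical(a$intensity, c2$intensity))
})

test_that("zero abundance leaves baseline and noise only", {
  scen <- sim_scenario(snr = 30)
  sp <- simulate_spectrum(30000, 0, scen, seed = 2)
  pk <- deconvolve(preprocess(sp))
  expect_equal(nrow(pk), 0)
})

test_that("toy structures have the expected oracle counts", {
  # a path of n atoms always gives n - 1 products
  g <- parse_structure(chain_mol(4), attachment = 1)
  expect_equal(nrow(enumerate_cleavages(g)), 3)
  g2 <- parse_structure(star_mol(), attachment = 1)
  expect_equal(nrow(enumerate_cleavages(g2)), 6)
  # generator determinism
  expect_identical(make_toy_linker_payload(8, seed = 4),
                   make_toy_linker_payload(8, seed = 4))
})

test_that("grafted rings are valid and never cleaved", {
  for (seed in c(3, 6, 9, 12)) {
    g <- parse_structure(make_toy_linker_payload(7, seed = seed,
                                                 with_ring = TRUE),
                         attachment = 1)
    expect_equal(sum(g$bonds$is_ring), 5)
    cl <- enumerate_cleavages(g)
    broken <- unlist(lapply(strsplit(cl$broken_bonds, "+", fixed = TRUE),
                            as.integer))
    expect_false(any(g$bonds$is_ring[broken]))
  }
})

test_that("the bundled synthetic linker-payload parses with its maleimide", {
  g <- parse_structure(synthetic_pbd_linker_payload(),
                       attachment = maleimide_pattern())
  expect_equal(g$atoms$element[g$attachment_atom], "N")
  expect_equal(formula_string(mol_formula(g)), "C22H24N2O3")
  # every retained fragment keeps the maleimide nitrogen
  cl <- enumerate_cleavages(g)
  expect_true(all(grepl("N", cl$retained_formula)))
})

test_that("simulated runs carry coherent truth, windows and scans", {
  scen <- sim_scenario(mz_step = 0.2, rt_range = c(1.6, 2.4), rt_step = 0.2)
  sim <- simulate_run(scen, subject = 1, time_h = 24, seed = 3)
  expect_false(is.unsorted(sim$run$rt))
  expect_true(all(c("species", "mass", "fraction") %in% names(sim$truth)))
  expect_true(all(sim$truth$fraction > 0))
  expect_equal(sim$windows$chain_id, c("LC", "HC"))
  # same seed, same subject: identical scans
  sim2 <- simulate_run(scen, subject = 1, time_h = 24, seed = 3)
  expect_identical(sim$run$peaks[[3]], sim2$run$peaks[[3]])
})
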