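test_that("chain masses follow residue additivity and disulfide correction", {
  expect_equal(chain_mass("G"), 75.03203, tolerance = 1e-5)
  expect_equal(chain_mass("GG"), 132.05349, tolerance = 1e-5)
  expect_equal(chain_mass("CC", n_disulfides = 1), 222.01276, tolerance = 1e-5)
  expect_error(chain_mass("GXZ"), "position 2")
  # average >= monoisotopic for anything with carbon
  expect_gt(chain_mass("PEPTIDE", mode = "average"), chain_mass("PEPTIDE"))
})

test_that("fixed modifications fire on the right termini", {
  expect_equal(apply_fixed_mods("QSVK"), -145.12151, tolerance = 1e-5)
  expect_equal(apply_fixed_mods("ASV"), 0)
  expect_equal(apply_fixed_mods("QSV"), -17.026549, tolerance = 1e-6)
  expect_equal(apply_fixed_mods("QSVK", lys_loss = FALSE), -17.026549,
               tolerance = 1e-6)
  expect_equal(apply_fixed_mods("QSVK", pyro_glu = FALSE), -128.09496,
               tolerance = 1e-5)
})

test_that("glycan masses match monosaccharide compositions", {
  expect_equal(glycan_mass("G0F"), 1444.5339, tolerance = 1e-3)
  expect_equal(glycan_mass("none"), 0)
  expect_equal(glycan_mass("G1F") - glycan_mass("G0F"), 162.05282,
               tolerance = 1e-5)
  expect_equal(glycan_mass("G0F") - glycan_mass("G0"), 146.05791,
               tolerance = 1e-5)
  expect_error(glycan_mass("G9"), "unknown glycan")
})

test_that("FASTA chains read with per-chain site conventions", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">LC light chain", "QSVLTQPPSASK", ">HC heavy chain",
               "EVQLVESGGGLVK"), f)
  ch <- read_chains(f)
  expect_equal(ch$chain_id, c("LC", "HC"))
  expect_equal(ch$n_sites, c(1L, 3L))
  expect_equal(ch$n_disulfides, c(2L, 4L))
})

hyd_only <- function() {
  lib <- expand_library(adcbiotx:::empty_cleavage_tbl(), parent = "C20H24N2O4")
  lib[lib$name == "hydrolysis", ]
}

lc_chain <- tibble::tibble(chain_id = "LC", sequence = "ACDEFGHIK",
                           n_sites = 1L, n_disulfides = 0L)

test_that("a 1-site chain with hydrolysis library yields the 4 candidates", {
  cand <- enumerate_candidates(lc_chain, conjugate_mono = 1000,
                               conjugate_avg = 1000.6, library = hyd_only())
  expect_setequal(cand$label,
                  c("LC", "LC + 1Cys", "LC + 1PL", "LC + 1PL + 1H2O"))
})

test_that("dar 0 with no caps and no glycans leaves the bare chain", {
  cand <- enumerate_candidates(lc_chain, conjugate_mono = 1000,
                               dar_range = 0, cys_cap = FALSE)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$label, "LC")
})

test_that("a DAR-3 chain builds the 0..3 hydrolysis ladder", {
  hc <- tibble::tibble(chain_id = "HC", sequence = "ACDEFGHIKLMNPQRSTVWY",
                       n_sites = 3L, n_disulfides = 0L)
  cand <- enumerate_candidates(hc, conjugate_mono = 1000, library = hyd_only(),
                               glycans = "G0F", cys_cap = FALSE)
  ladder <- paste0("HC + 3PL + ", 1:3, "H2O + G0F")
  expect_true(all(c("HC + 3PL + G0F", ladder) %in% cand$label))
  k <- 0:3
  masses <- cand$theo_mono_mass[match(c("HC + 3PL + G0F", ladder), cand$label)]
  expect_equal(diff(masses), rep(18.010565, 3), tolerance = 1e-6)
})

test_that("candidate masses are independently additive and labels invert", {
  lib <- expand_library(
    enumerate_cleavages(parse_structure(make_mol("frag", c("N", "C", "C", "O"),
      list(c(1, 2, 1L), c(2, 3, 1L), c(3, 4, 1L))), attachment = 1)),
    parent = "C3H9NO")
  cand <- enumerate_candidates(lc_chain, conjugate_mono = 800,
                               conjugate_avg = 800.5,
                               library = lib, glycans = c("none", "G0F"))
  cys <- 119.004100
  base <- chain_mass(lc_chain$sequence, 0) + apply_fixed_mods(lc_chain$sequence)
  for (r in seq_len(nrow(cand))) {
    p <- parse_label(cand$label[r])
    mods_mass <- if (length(p$mods)) {
      sum(p$mods * lib$delta_mono[match(names(p$mods), lib$name)])
    } else 0
    expect_equal(cand$theo_mono_mass[r],
                 base + p$dar * 800 + p$caps * cys +
                   glycan_mass(p$glycan) + mods_mass,
                 tolerance = 1e-6, info = cand$label[r])
    expect_equal(p$chain_id, cand$chain_id[r])
    expect_equal(p$dar, cand$dar[r])
    expect_equal(p$caps, cand$caps[r])
    expect_equal(p$glycan, cand$glycan[r])
  }
  expect_true(all(cand$theo_avg_mass >= cand$theo_mono_mass))
  expect_false(is.unsorted(cand$theo_mono_mass))
})

test_that("candidate counts follow the closed-form law for s <= 4", {
  for (s in 1:4) {
    for (g in 1:2) {
      ch <- tibble::tibble(chain_id = "X", sequence = "ACDEFGHIK",
                           n_sites = s, n_disulfides = 0L)
      cand <- enumerate_candidates(ch, conjugate_mono = 900,
                                   library = hyd_only(),
                                   glycans = c("none", "G0F")[seq_len(g)])
      expected <- sum(vapply(0:s, function(d) (s - d + 1) * (d + 1) * g,
                             numeric(1)))
      expect_equal(nrow(cand), expected, info = paste("s =", s, "g =", g))
    }
  }
})

test_that("the combinatorial guard trips on explosive candidate spaces", {
  big_lib <- tibble::tibble(name = paste0("m", 1:50),
                            delta_mono = seq(10, 500, length.out = 50),
                            delta_avg = seq(10, 500, length.out = 50))
  hc <- tibble::tibble(chain_id = "HC", sequence = "ACDEFGHIK",
                       n_sites = 3L, n_disulfides = 0L)
  expect_error(enumerate_candidates(hc, conjugate_mono = 1000,
                                    library = big_lib,
                                    max_candidates = 1000),
               "restrict")
})

test_that("candidate CSV round-trips", {
  cand <- enumerate_candidates(lc_chain, conjugate_mono = 1000,
                               library = hyd_only())
  f <- withr::local_tempfile(fileext = ".csv")
  write_candidates(cand, f)
  back <- read_candidates(f)
  expect_equal(back$label, cand$label)
  expect_equal(back$theo_avg_mass, cand$theo_avg_mass, tolerance = 1e-9)
})
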