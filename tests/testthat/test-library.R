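test_that("library size follows (m+1)c + m and skips nothing with nitrogen", {
  g <- parse_structure(synthetic_pbd_linker_payload(),
                       attachment = maleimide_pattern())
  cl <- enumerate_cleavages(g, max_bonds = 2)
  lib <- expand_library(cl, parent = g)
  expect_equal(nrow(lib), 4 * nrow(cl) + 3)
  expect_equal(anyDuplicated(lib$name), 0)
  expect_true(all(lib$neutral_mono_mass > 0))
})

test_that("parent-only expansion gives one entry per biotransformation", {
  lib <- expand_library(adcbiotx:::empty_cleavage_tbl(), parent = "C10H14N2O4")
  expect_equal(nrow(lib), 3)
  expect_setequal(lib$name,
                  c("hydrolysis", "deamidation", "hydrolysis + deamidation"))
  hyd <- lib[lib$name == "hydrolysis", ]
  expect_equal(hyd$formula_delta_vs_parent, "H2O")
  expect_equal(hyd$delta_mono, 18.010565, tolerance = 1e-6)
  expect_equal(hyd$delta_avg, 18.015, tolerance = 1e-3)
})

test_that("one cleavage expands to 4c + m = 7 entries", {
  g <- parse_structure(make_mol("amine chain", c("N", "C", "C"),
                                list(c(1, 2, 1L), c(2, 3, 1L))),
                       attachment = 1)
  cl <- enumerate_cleavages(g, max_bonds = 1)[1, ]
  lib <- expand_library(cl, parent = g)
  expect_equal(nrow(lib), 7)
})

test_that("cardinality law holds across nitrogen-rooted structures", {
  mols <- list(
    # N-rooted chain, star and branched shapes: the attachment nitrogen is
    # in every retained fragment, so no modification is ever skipped
    make_mol("n-chain", c("N", "C", "C", "C", "O"),
             list(c(1, 2, 1L), c(2, 3, 1L), c(3, 4, 1L), c(4, 5, 1L))),
    make_mol("n-star", c("N", "C", "C", "C"),
             list(c(1, 2, 1L), c(1, 3, 1L), c(1, 4, 1L))),
    make_mol("n-branched", c("N", "C", "C", "O", "C", "C"),
             list(c(1, 2, 1L), c(2, 3, 1L), c(3, 4, 1L), c(2, 5, 1L),
                  c(5, 6, 1L))))
  mods <- default_biotransformations()
  for (m in mols) {
    g <- parse_structure(m, attachment = 1)
    cl <- enumerate_cleavages(g)
    lib <- expand_library(cl, mods, parent = g)
    expect_equal(nrow(lib), (nrow(mods) + 1) * nrow(cl) + nrow(mods))
  }
})

test_that("non-physical modifications are skipped with a warning", {
  g <- parse_structure(example_mol("ethanol"), attachment = 1)
  cl <- enumerate_cleavages(g)
  # no nitrogen anywhere: deamidation and the combination cannot apply
  expect_warning(lib <- expand_library(cl, parent = g), "skipped")
  expect_equal(nrow(lib), 2 * nrow(cl) + 1)
  expect_false(any(grepl("deamidation", lib$name)))
})

test_that("the library CSV round-trips losslessly", {
  g <- parse_structure(synthetic_pbd_linker_payload(),
                       attachment = maleimide_pattern())
  lib <- expand_library(enumerate_cleavages(g), parent = g)
  f <- withr::local_tempfile(fileext = ".csv")
  write_library(lib, f)
  expect_equal(length(readLines(f)), nrow(lib) + 1)  # header + data rows
  back <- read_library(f)
  expect_equal(back$name, lib$name)
  expect_equal(back$neutral_mono_mass, lib$neutral_mono_mass, tolerance = 1e-9)
  expect_equal(back$delta_mono, lib$delta_mono, tolerance = 1e-6)
  expect_equal(back$formula_delta_vs_parent, lib$formula_delta_vs_parent)
})

test_that("duplicate-formula cleavages get distinct suffixed names", {
  g <- parse_structure(star_mol(), attachment = 1)
  lib <- suppressWarnings(expand_library(enumerate_cleavages(g), parent = g))
  expect_equal(anyDuplicated(lib$name), 0)
  expect_true(any(grepl("\\([0-9]+\\)$", lib$name)))
})

test_that("names follow the loss-of-formula convention", {
  g <- parse_structure(chain_mol(4), attachment = 1)
  lib <- suppressWarnings(expand_library(enumerate_cleavages(g), parent = g))
  expect_true(all(grepl("^loss of |^hydrolysis$|^deamidation$|^hydrolysis \\+ deamidation$",
                        lib$name)))
})
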