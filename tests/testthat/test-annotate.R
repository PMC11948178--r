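test_that("ppm accuracy matches hand-computed values", {
  expect_equal(compute_ppm(24758, 24758), 0)
  expect_equal(compute_ppm(24757.85, 24758), -6.058, tolerance = 1e-3)
  expect_equal(round(compute_ppm(52076.36, 52076)), 7)
  expect_equal(compute_ppm(100, 200), -5e5)
  expect_error(compute_ppm(100, 0), "positive")
})

test_that("peaks match candidates within an inclusive absolute tolerance", {
  cand <- toy_candidates(c(24758, 24777), c("LC + 1PL + 1H2O", "LC + other"))
  pk <- tibble::tibble(chain_id = "LC", neutral_mass = 24757.85, intensity = 10)
  ann <- match_peaks(pk, cand, tolerance_da = 3)
  expect_equal(nrow(ann), 1)
  expect_equal(ann$label, "LC + 1PL + 1H2O")
  expect_equal(round(ann$ppm), -6)
  expect_false(ann$review_flag)
  # exactly on the boundary still matches
  pk3 <- tibble::tibble(chain_id = "LC", neutral_mass = 24761, intensity = 1)
  expect_equal(match_peaks(pk3, cand, tolerance_da = 3)$label, "LC + 1PL + 1H2O")
})

test_that("an exact match has ppm 0 and rank 1", {
  cand <- toy_candidates(c(30000, 30100))
  pk <- tibble::tibble(chain_id = "LC", neutral_mass = 30000, intensity = 1)
  ann <- match_peaks(pk, cand)
  expect_equal(ann$ppm, 0)
  expect_equal(ann$rank, 1L)
  expect_equal(ann$n_alternatives, 1L)
})

test_that("equidistant candidates tie-break to the lower mass and flag review", {
  cand <- toy_candidates(c(29998, 30002))
  pk <- tibble::tibble(chain_id = "LC", neutral_mass = 30000, intensity = 1)
  ann <- match_peaks(pk, cand, tolerance_da = 3)
  expect_equal(nrow(ann), 2)
  expect_equal(ann$theo_mass[ann$rank == 1], 29998)
  expect_true(all(ann$review_flag))
  expect_equal(unique(ann$n_alternatives), 2L)
})

test_that("unmatched peaks emit an unidentified record", {
  cand <- toy_candidates(25000)
  pk <- tibble::tibble(chain_id = "LC", neutral_mass = 60000, intensity = 3)
  ann <- match_peaks(pk, cand)
  expect_equal(nrow(ann), 1)
  expect_true(is.na(ann$label))
  expect_equal(ann$n_alternatives, 0L)
  expect_error(match_peaks(pk, cand[0, ]), "empty candidate")
})

test_that("matching respects chain-specific candidate sets", {
  cand <- dplyr::bind_rows(toy_candidates(24000, "LC sp", "LC"),
                           toy_candidates(24001, "HC sp", "HC"))
  pk <- tibble::tibble(chain_id = "HC", neutral_mass = 24000.5, intensity = 1)
  ann <- match_peaks(pk, cand)
  expect_equal(ann$label, "HC sp")
})

test_that("every record satisfies the ppm-tolerance bound and symmetry", {
  withr::local_seed(8)
  cand <- toy_candidates(sort(runif(20, 20000, 60000)))
  pk <- tibble::tibble(chain_id = "LC",
                       neutral_mass = runif(30, 20000, 60000),
                       intensity = runif(30))
  ann <- match_peaks(pk, cand, tolerance_da = 3)
  hit <- ann[!is.na(ann$ppm), ]
  expect_true(all(abs(hit$ppm) <= 3 / hit$theo_mass * 1e6 + 1e-9))
  expect_true(all(abs(hit$delta_da) <= 3))
  # mirroring all masses flips the delta signs but keeps the match set
  ann2 <- match_peaks(dplyr::mutate(pk, neutral_mass = -neutral_mass + 80000),
                      dplyr::mutate(cand,
                                    theo_avg_mass = -theo_avg_mass + 80000,
                                    theo_mono_mass = theo_avg_mass),
                      tolerance_da = 3)
  expect_equal(sum(!is.na(ann2$ppm)), nrow(hit))
})

test_that("matching is deterministic", {
  cand <- toy_candidates(c(30000, 30001, 40000))
  pk <- tibble::tibble(chain_id = "LC", neutral_mass = c(30000.4, 39999),
                       intensity = c(1, 2))
  a <- match_peaks(pk, cand)
  b <- match_peaks(pk, cand)
  expect_identical(a, b)
})

make_ann <- function(presence) {
  # presence: named list species -> time points where observed (of 1..6)
  times <- 1:6
  rows <- list()
  for (tp in times) {
    for (s in names(presence)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample_id = paste0("T", tp), subject = 1L, time_h = tp,
        chain_id = "LC", neutral_mass = 25000,
        intensity = if (tp %in% presence[[s]]) 5 else 0,
        label = s, rank = 1L)
    }
  }
  dplyr::bind_rows(rows)
}

test_that("consolidation keeps species by time-point fraction, inclusive", {
  ann <- make_ann(list(always = 1:6, half = 1:3, once = 2))
  out <- consolidate(ann, min_timepoint_fraction = 0.5)
  expect_setequal(unique(out$species), c("always", "half"))  # 3/6 boundary kept
  expect_false("once" %in% out$species)
  # absent measurements appear as zero rows
  half <- out[out$species == "half", ]
  expect_equal(nrow(half), 6)
  expect_equal(sum(half$intensity == 0), 3)
})

test_that("consolidation at threshold zero keeps everything observed", {
  ann <- make_ann(list(once = 2))
  out <- consolidate(ann, min_timepoint_fraction = 0)
  expect_equal(unique(out$species), "once")
})
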