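test_that("fractional abundances normalise to one", {
  expect_equal(fractional_abundance(c(80, 20)), c(0.8, 0.2))
  expect_equal(fractional_abundance(5), 1)
  expect_equal(fractional_abundance(c(1, 1, 2)), c(0.25, 0.25, 0.5))
  expect_lt(abs(sum(fractional_abundance(runif(50))) - 1), 1e-12)
  expect_warning(z <- fractional_abundance(c(0, 0)), "zero")
  expect_equal(z, c(0, 0))
  expect_error(fractional_abundance(c(-1, 2)), "non-negative")
})

test_that("fractions are invariant to intensity rescaling", {
  withr::local_seed(2)
  x <- runif(10)
  expect_equal(fractional_abundance(x), fractional_abundance(1e6 * x))
})

test_that("percent difference follows the mean-denominator formula", {
  expect_equal(percent_difference(0.3, 0.3), 0)
  expect_equal(percent_difference(0.25, 0.20), 22.2222, tolerance = 1e-4)
  expect_equal(percent_difference(0, 0.2), -200)
  expect_equal(percent_difference(0.2, 0, sign = "old_minus_new"), -200)
  expect_true(is.na(percent_difference(0, 0)))
})

test_that("replicate aggregation uses the n-1 standard deviation", {
  ps <- tibble::tibble(species = "A", subject = 1:3, time_h = 24,
                       fraction = c(0.1, 0.2, 0.3))
  tc <- aggregate_replicates(ps)
  expect_equal(tc$mean_fraction, 0.2)
  expect_equal(tc$sd_fraction, 0.1)
  expect_equal(tc$n_subjects, 3L)
  flat <- aggregate_replicates(dplyr::mutate(ps, fraction = 0.2))
  expect_equal(flat$sd_fraction, 0)
  single <- aggregate_replicates(ps[1, ])
  expect_equal(single$mean_fraction, 0.1)
  expect_equal(single$sd_fraction, 0)
})

test_that("per-sample fractions conserve mass within chain groups", {
  tbl <- tidyr::crossing(species = c("a", "b", "c"),
                         sample_id = c("s1", "s2"),
                         chain_id = c("LC", "HC")) |>
    dplyr::mutate(subject = 1L, time_h = 1,
                  intensity = seq_len(dplyr::n()))
  out <- per_sample_fractions(tbl)
  sums <- out |>
    dplyr::group_by(.data$sample_id, .data$chain_id) |>
    dplyr::summarise(s = sum(.data$fraction), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-12))
})

test_that("unidentified species stay out of the denominator by default", {
  tbl <- tibble::tibble(
    species = c("A", "unidentified m/25000"),
    sample_id = "s1", chain_id = "LC", subject = 1L, time_h = 1,
    intensity = c(60, 40))
  out <- per_sample_fractions(tbl)
  expect_equal(out$fraction[out$species == "A"], 1)
  out2 <- per_sample_fractions(tbl, include_unidentified = TRUE)
  expect_equal(sort(out2$fraction), c(0.4, 0.6))
})

test_that("known fractions are recovered under replicate noise", {
  withr::local_seed(77)
  truth <- c(A = 0.55, B = 0.3, C = 0.15)
  rows <- list()
  for (subj in 1:3) {
    noisy <- truth * exp(rnorm(3, 0, 0.1))  # CV 10% multiplicative
    rows[[subj]] <- tibble::tibble(
      species = names(truth), sample_id = paste0("s", subj),
      subject = subj, time_h = 24, chain_id = "LC", intensity = noisy * 1e5)
  }
  tc <- quantify_timecourse(dplyr::bind_rows(rows))
  est <- tc$mean_fraction[match(names(truth), tc$species)]
  expect_lt(mean(abs(est - truth)), 0.05)
})

test_that("tidy, glance and autoplot work on a timecourse", {
  ps <- tidyr::crossing(species = c("A", "B"), subject = 1:2,
                        time_h = c(1, 24)) |>
    dplyr::mutate(fraction = 0.5)
  tc <- aggregate_replicates(ps)
  td <- tidy(tc)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "adc_timecourse"))
  gl <- glance(tc)
  expect_equal(gl$n_species, 2)
  expect_equal(gl$n_timepoints, 2)
  expect_s3_class(autoplot(tc), "ggplot")
})
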