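test_that("Golgi position index follows (a + b) / 2L with its extremes", {
  expect_equal(golgi_position_index(10, 4, 6), 0.5)
  expect_equal(golgi_position_index(7, 7, 7), 1)
  expect_equal(golgi_position_index(7, 0, 0), 0)
  expect_error(golgi_position_index(0, 0, 0), "measurement error")
  expect_error(golgi_position_index(10, 6, 4), "measurement error")
  expect_error(golgi_position_index(10, 2, 11), "measurement error")
  # anterior-posterior reflection: index(reflected) = 1 - index(original)
  set.seed(8)
  for (rep in 1:20) {
    L <- runif(1, 1, 20)
    ab <- sort(runif(2, 0, L))
    expect_equal(golgi_position_index(L, L - ab[2], L - ab[1]),
                 1 - golgi_position_index(L, ab[1], ab[2]))
  }
})

test_that("apical/basal ratio sums the end fractions of arc length", {
  prof <- intensity_profile(1:10, c(1, 1, 1, 0, 0, 0, 0, 2, 2, 2))
  expect_equal(apical_basal_signal_ratio(prof, 0.3), 0.5)
  flat <- intensity_profile(1:10, rep(3, 10))
  expect_equal(apical_basal_signal_ratio(flat), 1)
  # reflection inverts the ratio when both sums are positive
  refl <- intensity_profile(1:10, rev(prof$values))
  expect_equal(apical_basal_signal_ratio(refl, 0.3),
               1 / apical_basal_signal_ratio(prof, 0.3))
  # all signal in the final fraction: defined (0), reversed is undefined
  tail_only <- intensity_profile(1:10, c(rep(0, 7), 2, 2, 2))
  expect_lt(apical_basal_signal_ratio(tail_only, 0.3), 1)
  expect_error(
    apical_basal_signal_ratio(intensity_profile(1:10, c(2, 2, 2, rep(0, 7))),
                              0.3),
    "undefined-ratio")
  expect_error(apical_basal_signal_ratio(flat, 0.7), "fraction")
})

test_that("kymograph velocity converts angles under the stated convention", {
  expect_equal(kymograph_velocity(45, 1, 1), 1)
  expect_equal(kymograph_velocity(0, 1, 1), 0)
  expect_equal(kymograph_velocity(30, 0.5, 2), tan(pi / 6) * 0.25)
  expect_equal(kymograph_velocity(-45, 1, 1), -1)
  expect_error(kymograph_velocity(90, 1, 1), "angle")
})

test_that("count-based rates behave", {
  expect_equal(positive_fraction(0, 8), 0)
  expect_equal(positive_fraction(12, 12), 1)
  expect_equal(positive_fraction(3, 12), 0.25)
  expect_error(positive_fraction(1, 0), "undefined-rate")
  expect_error(positive_fraction(5, 3), "n_pos")
  expect_equal(nuclear_cytoplasmic_ratio(2, 1), 2)
  expect_equal(nuclear_cytoplasmic_ratio(1, 1), 1)
  expect_equal(nuclear_cytoplasmic_ratio(0, 3), 0)
  expect_error(nuclear_cytoplasmic_ratio(1, 0), "positive")
})

test_that("paired-profile normalization implements the five printed steps", {
  # flat signal over flat reference: every bin exactly 1
  pos <- seq(0, 100, length.out = 200)
  flat <- paired_profile(pos, rep(5, 200), rep(2, 200))
  out <- normalize_paired_profile(flat, filter_window = 11, n_bins = 20)
  expect_equal(out$value, rep(1, 20))

  # narrow reference spikes are removed by the running-minimum baseline:
  # output identical to the spike-free case
  ref <- rep(2, 200)
  spiked <- ref
  spiked[c(40, 41, 120)] <- 9
  sig <- 1 + pos / 100
  out_clean <- normalize_paired_profile(paired_profile(pos, sig, ref))
  out_spiked <- normalize_paired_profile(paired_profile(pos, sig, spiked))
  expect_equal(out_spiked$value, out_clean$value)
  # and the baseline filter agrees with a brute-force running minimum
  expect_equal(as.numeric(zoo::rollapply(zoo::zoo(spiked), 11, min,
                                         partial = TRUE, align = "center")),
               brute_running_min(spiked, 11))

  # linear ramp over constant reference: bin means recover the ramp's
  # bin-center values rescaled to max 1, within discretization error
  ramp <- paired_profile(pos, pos, rep(1, 200))
  out_r <- normalize_paired_profile(ramp, n_bins = 20)
  expected <- out_r$center / max(out_r$center)
  expect_lt(max(abs(out_r$value - expected)), 0.02)
  expect_equal(max(out_r$value), 1)

  # invariances: common positive scaling of both channels; signal-only scaling
  sc1 <- normalize_paired_profile(paired_profile(pos, 7 * sig, 7 * ref))
  sc2 <- normalize_paired_profile(paired_profile(pos, 3.3 * sig, ref))
  expect_equal(sc1$value, out_clean$value)
  expect_equal(sc2$value, out_clean$value)

  # guards
  expect_error(normalize_paired_profile(flat, filter_window = 4), "odd")
  expect_error(normalize_paired_profile(
    paired_profile(pos, sig, rep(0, 200))), "normalization error")
})
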