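test_that("snr_map implements 20*log10(mean/sd) with an explicit validity mask", {
  # identical realizations: zero std everywhere -> all invalid
  v <- random_volume(4, 8)
  r <- snr_map(list(v, v, v))
  expect_false(any(r$valid_mask))
  expect_true(all(is.na(r$snr_db)))

  # Gaussian stack mu=100 sd=10: median SNR = 20*log10(10) = 20 dB
  set.seed(21)
  g <- array(rnorm(8^3 * 1000, 100, 10), c(8, 8, 8, 1000))
  rg <- snr_map(g)
  expect_equal(rg$summary, 20, tolerance = 0.5 / 20)
  expect_equal(rg$n_realizations, 1000L)

  # Poisson stack lambda=100: same closed form via shot-noise scaling
  set.seed(22)
  p <- array(rpois(8^3 * 1000, 100), c(8, 8, 8, 1000))
  rp <- snr_map(p)
  expect_equal(rp$summary, 20, tolerance = 0.5 / 20)

  # invariance under global positive rescaling
  rs <- snr_map(g * 37.5)
  expect_equal(rs$snr_db, rg$snr_db, tolerance = 1e-10)

  expect_error(snr_map(list(v)), "at least 2")
  expect_error(snr_map(list(v, random_volume(5, 1))), "shape")
})

test_that("delta_snr summarises improvements and the photon multiplier", {
  set.seed(33)
  g <- array(rnorm(6^3 * 200, 100, 10), c(6, 6, 6, 200))
  before <- snr_map(g)
  same <- delta_snr(before, before)
  expect_equal(same$median_all, 0)
  expect_equal(unname(same$mf), 1)

  # a uniform +10 dB improvement: noise sd divided by sqrt(10)
  set.seed(34)
  g2 <- array(rnorm(6^3 * 200, 100, 10 / sqrt(10)), c(6, 6, 6, 200))
  after <- snr_map(g2)
  d <- delta_snr(before, after)
  expect_equal(d$median_all, 10, tolerance = 0.1)
  expect_equal(unname(d$mf), 10, tolerance = 0.25)
  expect_true(all(d$effective_mask[!is.na(d$delta_db)] ==
                    (d$delta_db[!is.na(d$delta_db)] > 3)))
})

test_that("photon_multiplier and expected_gain are exact inverses", {
  expect_equal(photon_multiplier(0), 1)
  expect_equal(photon_multiplier(10), 10)
  expect_equal(photon_multiplier(5.4), 3.467, tolerance = 1e-3)
  expect_equal(expected_gain(10), 10)
  expect_equal(expected_gain(1), 0)
  expect_equal(expected_gain(3.5), 5.44, tolerance = 1e-3)
  for (c in c(0.1, 1, 2, 3.5, 10, 100))
    expect_equal(photon_multiplier(expected_gain(c)), c, tolerance = 1e-12)
  expect_error(photon_multiplier(Inf), "finite")
  expect_error(expected_gain(0), "positive")
})
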