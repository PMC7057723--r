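test_that("box_filter matches direct neighbourhood means, with boundary clipping", {
  # impulse: centre of a 3^3 volume spreads to 27ths
  imp <- volume3d(array(0, c(3, 3, 3)))
  imp$data[2, 2, 2] <- 27
  expect_equal(box_filter(imp, 1)$data[2, 2, 2], 1.0)

  c7 <- volume3d(array(7, c(5, 5, 5)))
  expect_equal(box_filter(c7, 2)$data, array(7, c(5, 5, 5)))

  v <- random_volume(8, 42)
  got <- box_filter(v, 1)$data
  d <- dim(v$data)
  for (idx in list(c(1, 1, 1), c(8, 8, 8), c(4, 5, 3), c(1, 8, 4))) {
    xr <- max(1, idx[1] - 1):min(d[1], idx[1] + 1)
    yr <- max(1, idx[2] - 1):min(d[2], idx[2] + 1)
    zr <- max(1, idx[3] - 1):min(d[3], idx[3] + 1)
    expect_equal(got[idx[1], idx[2], idx[3]],
                 mean(v$data[xr, yr, zr]), tolerance = 1e-12)
  }
})

test_that("residual_map is zero on constants and on interior of a linear ramp", {
  c2 <- volume3d(array(2, c(4, 4, 4)))
  expect_equal(residual_map(c2, 1)$data, array(0, c(4, 4, 4)))

  ramp <- volume3d(array(rep(1:6, times = 25), c(6, 5, 5)))
  r <- residual_map(ramp, 1)$data
  expect_equal(max(abs(r[2:5, 2:4, 2:4])), 0, tolerance = 1e-12)

  v <- random_volume(8, 7)
  r2 <- residual_map(v, 1)$data
  expect_equal(r2, v$data - box_filter(v, 1)$data, tolerance = 1e-12)
})

test_that("adaptive_sigma2 matches the brute-force padded pipeline", {
  p <- filter_params(rV = 2L, rP = 1L)
  v <- random_volume(8, 19)
  got <- adaptive_sigma2(v, p)$data
  want <- oracle_precompute(v$data, p)$sigma2
  expect_equal(got, want, tolerance = 1e-10)

  # min bound: sigma2(xi) never exceeds the local estimate at xi itself
  expect_true(all(got <= oracle_precompute(v$data, p)$s2core + 1e-12))

  # constant volume: all residuals zero -> floor everywhere
  pf <- filter_params(rV = 2L, rP = 1L, min_sigma = 0.5)
  cv <- volume3d(array(3, c(6, 6, 6)))
  expect_equal(adaptive_sigma2(cv, pf)$data, array(0.25, c(6, 6, 6)))
})

test_that("patch_distance2 is a normalised squared L2 distance", {
  arr <- array(runif(6^3), c(6, 6, 6))
  expect_equal(patch_distance2(arr, c(3, 3, 3), c(3, 3, 3), 1), 0)

  a <- array(0, c(7, 7, 7)); a[1:3, 1:3, 1:3] <- 0; a[5:7, 5:7, 5:7] <- 1
  expect_equal(patch_distance2(a, c(2, 2, 2), c(6, 6, 6), 1), 1)

  set.seed(5)
  b <- array(rnorm(7^3), c(7, 7, 7))
  pi_ <- b[2:4, 2:4, 2:4]; pj_ <- b[4:6, 3:5, 2:4]
  expect_equal(patch_distance2(b, c(3, 3, 3), c(5, 4, 3), 1),
               sum((pi_ - pj_)^2) / 27, tolerance = 1e-12)
})

test_that("preselect applies the mean- and variance-ratio gates", {
  p <- filter_params(rV = 2L, rP = 1L)
  v <- random_volume(8, 23)
  pre <- anlm_precompute(v, p)
  expect_true(preselect(pre, c(4, 4, 4), c(4, 4, 4), p))

  # a 100x brighter region fails the mean-ratio gate
  w <- volume3d(array(c(rep(1, 4 * 8 * 8), rep(100, 4 * 8 * 8)), c(8, 8, 8)))
  prew <- anlm_precompute(w, p)
  expect_false(preselect(prew, c(4, 4, 2), c(4, 4, 7), p))

  # decisions match direct evaluation of both ratio tests
  bm <- pre$box_mean$data; bv <- pre$box_var$data
  set.seed(31)
  for (k in 1:50) {
    xi <- sample(3:6, 3, replace = TRUE)
    xj <- sample(3:6, 3, replace = TRUE)
    mr <- bm[xi[1], xi[2], xi[3]] / bm[xj[1], xj[2], xj[3]]
    vr <- bv[xi[1], xi[2], xi[3]] / bv[xj[1], xj[2], xj[3]]
    want <- mr >= 0.95 && mr <= 1 / 0.95 && vr >= 0.5 && vr <= 2
    expect_identical(preselect(pre, xi, xj, p), want)
  }
})

test_that("filter_pass matches the naive quadruple-loop reference", {
  for (case in list(list(n = 8, p = filter_params(rV = 2L, rP = 1L)),
                    list(n = 10, p = filter_params(rV = 3L, rP = 2L)),
                    list(n = 8, p = filter_params(rV = 2L, rP = 1L,
                                                  noise_model = "rician")))) {
    v <- random_volume(case$n, 100 + case$n)
    ref <- oracle_filter_pass(v$data, case$p)
    want <- ref$filtered
    if (case$p$noise_model == "rician") {
      s2 <- oracle_precompute(v$data, case$p)$sigma2
      want <- sqrt(pmax(want - 2 * s2, 0))
    }
    got <- filter_pass(v, case$p)$data
    expect_equal(got, want, tolerance = 1e-5)
    # normalisation: weights sum to one after division by Zi
    expect_lt(ref$worst_norm, 1e-6)
  }
})

test_that("constant volumes are fixed points; output is a convex combination", {
  cv <- volume3d(array(4.5, c(9, 9, 9)))
  p <- filter_params(rP = 1L)
  expect_identical(filter_pass(cv, p)$data, cv$data)
  d <- anlm_denoise(cv)
  expect_equal(d$data, cv$data, tolerance = 1e-12)

  v <- random_volume(10, 55, offset = 0)
  f <- filter_pass(v, filter_params(rP = 1L))$data
  expect_true(all(f >= 0))
  expect_true(all(f <= max(v$data) + 1e-12))
  expect_true(all(f >= min(v$data) - 1e-12))
})

test_that("vanishing bandwidth scale collapses the filter onto the input", {
  v <- random_volume(8, 77)
  f <- filter_pass(v, filter_params(rP = 1L, beta = 1e-12))$data
  expect_equal(f, v$data, tolerance = 1e-6)
})

test_that("log10-scale input is refused", {
  v <- volume3d(array(1, c(6, 6, 6)), scale = "log10")
  expect_error(filter_pass(v, filter_params(rP = 1L)), "linear")
})

test_that("rician_correct implements the clamped second-moment correction", {
  m2 <- volume3d(array(9, c(2, 2, 2)))
  expect_equal(rician_correct(m2, array(2, c(2, 2, 2)))$data,
               array(sqrt(5), c(2, 2, 2)))
  expect_equal(rician_correct(m2, array(4.5, c(2, 2, 2)))$data,
               array(0, c(2, 2, 2)))
  expect_equal(rician_correct(m2, array(0, c(2, 2, 2)))$data,
               array(3, c(2, 2, 2)))
})

test_that("params and mixing passes are validated", {
  expect_error(filter_params(rV = 2L, rP = 2L), "strictly smaller")
  expect_error(anlm_denoise(random_volume(6, 1),
                            filter_params(rP = 1L),
                            filter_params(rP = 2L, beta = 2)),
               "differ only in rP")
})
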