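test_that("constant volumes have energy only in the approximation band", {
  s <- dwt3(volume3d(array(3, c(8, 8, 8))))
  expect_equal(s$LLL, array(3 * 2^1.5, c(4, 4, 4)), tolerance = 1e-12)
  for (nm in setdiff(subband_names_all(), "LLL"))
    expect_equal(max(abs(s[[nm]])), 0, tolerance = 1e-12)
})

test_that("dwt3/idwt3 reconstruct exactly, including odd extents", {
  for (d in list(c(8, 8, 8), c(7, 8, 9), c(5, 5, 5), c(1, 4, 4))) {
    set.seed(sum(d))
    v <- volume3d(array(runif(prod(d)), d))
    r <- idwt3(dwt3(v))
    expect_equal(r$data, v$data, tolerance = 1e-10)
  }
  # inverse then forward is also a round trip on the coefficient side
  set.seed(9)
  v <- volume3d(array(runif(6^3), c(6, 6, 6)))
  s <- dwt3(v)
  s2 <- dwt3(idwt3(s))
  for (nm in subband_names_all())
    expect_equal(s2[[nm]], s[[nm]], tolerance = 1e-10)
})

test_that("the Haar transform preserves energy (Parseval)", {
  set.seed(4)
  v <- volume3d(array(runif(8^3), c(8, 8, 8)))
  s <- dwt3(v)
  e <- sum(vapply(subband_names_all(), function(nm) sum(s[[nm]]^2), 0))
  expect_equal(e, sum(v$data^2), tolerance = 1e-4 * sum(v$data^2))
})

test_that("sub-band mixing takes LLL from the large pass, details from the small", {
  set.seed(12)
  a <- volume3d(array(runif(8^3), c(8, 8, 8)))
  b <- volume3d(array(runif(8^3), c(8, 8, 8)))
  # mixing identical inputs is the identity
  expect_equal(subband_mix(a, a)$data, a$data, tolerance = 1e-10)
  # zero small-pass + constant large-pass: all details zero -> constant out
  z <- volume3d(array(0, c(8, 8, 8)))
  cc <- volume3d(array(2.5, c(8, 8, 8)))
  expect_equal(subband_mix(z, cc)$data, array(2.5, c(8, 8, 8)),
               tolerance = 1e-10)
  # equals the manually assembled sub-band set
  sa <- dwt3(a); sb <- dwt3(b)
  manual <- sa
  manual$LLL <- sb$LLL
  expect_equal(subband_mix(a, b)$data, idwt3(manual)$data, tolerance = 1e-10)
  expect_error(subband_mix(a, volume3d(array(0, c(4, 4, 4)))), "same shape")
})
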