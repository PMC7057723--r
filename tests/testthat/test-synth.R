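test_that("benchmark media carry the right optical properties and geometry", {
  b1 <- build_benchmark("B1", grid = 100)
  expect_true(all(b1$mua == 0.02) && all(b1$mus == 10) &&
                all(b1$g == 0.9) && all(b1$n == 1.37))

  b2 <- build_benchmark("B2", grid = 100)
  expect_equal(b2$mua[50, 50, 30], 0.1)
  expect_equal(b2$mua[1, 1, 1], 0.02)
  expect_identical(sum(b2$mua == 0.1), 64000L)
  expect_true(all(b2$n == 1.37))

  b3 <- build_benchmark("B3", grid = 100)
  expect_identical(sum(b3$n == 6.85), 64000L)
  expect_true(all(b3$mua == 0.02))

  # proportional scaling: at grid 50 the inclusion is a 20^3 cube
  b2s <- build_benchmark("B2", grid = 50)
  expect_identical(sum(b2s$mua == 0.1), 8000L)

  expect_error(build_benchmark("B4"), "arg")
})

test_that("mc_fluence conserves energy and is seed-deterministic", {
  m <- build_benchmark("B1", grid = 30)
  cfg <- sim_config(nphoton = 5000, source_pos = c(15, 15, 0), seed = 42L)
  v1 <- mc_fluence(m, cfg)
  e <- attr(v1, "energy")
  expect_equal(e$absorbed + e$escaped + e$killed,
               e$launched + e$boosted,
               tolerance = 1e-6)
  v2 <- mc_fluence(m, cfg)
  expect_identical(v1$data, v2$data)
  v3 <- mc_fluence(m, sim_config(nphoton = 5000, source_pos = c(15, 15, 0),
                                 seed = 43L))
  expect_false(identical(v1$data, v3$data))
  expect_true(all(v1$data >= 0))

  # refractive inclusion (Fresnel path) also conserves energy
  m3 <- build_benchmark("B3", grid = 30)
  e3 <- attr(mc_fluence(m3, cfg), "energy")
  expect_equal(e3$absorbed + e3$escaped + e3$killed,
               e3$launched + e3$boosted,
               tolerance = 1e-6)
})

test_that("an absorbing inclusion lowers the fluence beyond it", {
  cfg <- sim_config(nphoton = 2e4, source_pos = c(25, 25, 0), seed = 5L)
  f1 <- mc_fluence(build_benchmark("B1", grid = 50), cfg)
  f2 <- mc_fluence(build_benchmark("B2", grid = 50), cfg)
  # plane distal to the inclusion (inclusion spans z voxels 6..25)
  expect_lt(median(f2$data[, , 35][f1$data[, , 35] > 0]),
            median(f1$data[, , 35][f1$data[, , 35] > 0]))
})

test_that("diffusion_fluence follows the point-source Green's function", {
  m <- medium(0.02, 10, 0.9, 1.37, grid = 41)
  src <- c(20.5, 20.5, 20.5)
  phi <- diffusion_fluence(m, src)
  musp <- 10 * (1 - 0.9)
  expect_equal(musp, 1.0)
  D <- 1 / (3 * (0.02 + musp))
  mueff <- sqrt(3 * 0.02 * (0.02 + musp))
  expect_equal(mueff, 0.2474, tolerance = 1e-3)
  # closed form at r = 10 mm (voxel (30.5-0.5, ...) is 10 mm along x)
  expect_equal(phi$data[31, 21, 21],
               exp(-mueff * 10) / (4 * pi * D * 10), tolerance = 1e-9)
  # doubling r multiplies phi by exp(-mueff*r)/2
  r1 <- 8; r2 <- 16
  expect_equal(phi$data[21 + r2, 21, 21] / phi$data[21 + r1, 21, 21],
               exp(-mueff * r1) / 2, tolerance = 1e-9)
  # spherical symmetry across axes
  expect_equal(phi$data[21, 21 + 10, 21], phi$data[31, 21, 21],
               tolerance = 1e-9)
  # source voxel capped at the one-voxel-away value
  expect_equal(phi$data[21, 21, 21],
               exp(-mueff * 1) / (4 * pi * D * 1), tolerance = 1e-9)
  expect_error(diffusion_fluence(build_benchmark("B2", 20), c(1, 1, 1)),
               "homogeneous")
})

test_that("mc fluence agrees with diffusion at mid-range distances", {
  m <- build_benchmark("B1", grid = 50)
  src <- c(25, 25, 25)
  cfg <- sim_config(nphoton = 1e5, source_pos = src, seed = 77L,
                    launch = "isotropic")
  mc <- mc_fluence(m, cfg)
  di <- diffusion_fluence(m, src)
  cx <- (1:50) - 0.5
  r <- sqrt(outer(outer((cx - src[1])^2, (cx - src[2])^2, "+"),
                  (cx - src[3])^2, "+"))
  # shell-averaged comparison, 1-mm bins over 10-20 mm
  for (r0 in 10:19) {
    shell <- r >= r0 & r < r0 + 1
    rel <- mean(mc$data[shell]) / mean(di$data[shell]) - 1
    expect_lt(abs(rel), 0.15)
  }
})

test_that("shot noise has Poisson statistics and vanishes at large budgets", {
  phantom <- b1_diffusion_phantom(16)
  # law of large numbers: relative error shrinks at k = 1e9
  noisy <- add_shot_noise(phantom, 1e9, seed = 3L)
  rel <- abs(noisy$data - phantom$data) / phantom$data
  expect_lt(median(rel), 0.01)

  # zero-intensity voxels stay zero
  z <- volume3d(array(0, c(4, 4, 4))); z$data[1, 1, 1] <- 1
  nz <- add_shot_noise(z, 1000, seed = 1L)
  expect_true(all(nz$data[-1] == 0))

  # ensemble moments at lambda = 100 (one voxel, many seeds)
  flat <- volume3d(array(1, c(2, 2, 2)))
  counts <- vapply(1:1000, function(s)
    add_shot_noise(flat, 800, seed = s)$data[1, 1, 1] * 800 / 8, 0)
  expect_equal(mean(counts), 100, tolerance = 0.10)
  expect_equal(var(counts), 100, tolerance = 0.10)

  # reproducibility and RNG hygiene
  a <- add_shot_noise(phantom, 1e5, seed = 9L)
  b <- add_shot_noise(phantom, 1e5, seed = 9L)
  expect_identical(a$data, b$data)
  expect_error(add_shot_noise(volume3d(array(1, c(2, 2, 2)), scale = "log10"),
                              10), "linear")
})
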