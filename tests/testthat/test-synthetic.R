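test_that("P-SHG forward model evaluates to its closed-form values", {
  sc <- synthetic_scene(b_true = 2, phi_deg = 0, amplitude = 100,
                        offset = 0, noise = "none", dim = c(3, 4))
  st <- gen_pshg_stack(sc, angles_deg = c(0, 45, 90, 135, 170))
  expect_equal(unique(as.numeric(st$frames[[1]])), 400)  # A b^2
  expect_equal(unique(as.numeric(st$frames[[3]])), 100)  # A (0 + 1^2)
  expect_equal(unique(as.numeric(st$frames[[2]])), 325)  # A (1 + 1.5^2)
  expect_error(synthetic_scene(b_true = -1), "positive")
  expect_error(gen_pshg_stack(sc, angles_deg = c(0, 10, 20, 30)),
               "at least 5")
})

test_that("polarimetric channels satisfy the anisotropy identity", {
  # beta = 1: aligned limit, perpendicular channel identically zero
  sc1 <- synthetic_scene(beta_true = 1, noise = "none", dim = c(4, 4))
  ch1 <- gen_polarimetric_channels(sc1)
  expect_true(all(vapply(ch1$perp$frames, max, numeric(1)) == 0))
  # beta = 0: random limit, channels identical
  sc0 <- synthetic_scene(beta_true = 0, noise = "none", dim = c(4, 4))
  ch0 <- gen_polarimetric_channels(sc0)
  for (i in seq_along(ch0$par$frames))
    expect_equal(ch0$par$frames[[i]], ch0$perp$frames[[i]])
  # beta = 0.5 with total intensity 90 splits 72/18
  # (b = 2, phi = 0, A = 90 gives total exactly 90 at theta = 90 deg)
  sc <- synthetic_scene(b_true = 2, phi_deg = 0, amplitude = 90,
                        offset = 0, beta_true = 0.5, noise = "none",
                        dim = c(2, 2))
  ch <- gen_polarimetric_channels(sc, angles_deg = seq(0, 170, by = 10))
  i90 <- which(ch$par$angles_deg == 90)
  expect_equal(unique(as.numeric(ch$par$frames[[i90]])), 72)
  expect_equal(unique(as.numeric(ch$perp$frames[[i90]])), 18)
  # identity holds at every angle and pixel
  for (i in seq_along(ch$par$frames)) {
    p <- ch$par$frames[[i]]; q <- ch$perp$frames[[i]]
    expect_equal((p - q) / (p + 2 * q), matrix(0.5, 2, 2))
  }
  expect_error(synthetic_scene(beta_true = 1.2), "beta_true")
})

test_that("chiral pairs inject a multiplicative symmetric asymmetry", {
  base <- matrix(100, 5, 5)
  sc <- synthetic_scene(cd_epsilon = 1.0, noise = "none", dim = c(5, 5))
  pair <- gen_chiral_pair(sc, base = base)
  expect_equal(pair$lhcp, matrix(150, 5, 5))
  expect_equal(pair$rhcp, matrix(50, 5, 5))
  sc0 <- synthetic_scene(cd_epsilon = 0, noise = "none", dim = c(5, 5))
  pair0 <- gen_chiral_pair(sc0, base = base)
  expect_identical(pair0$lhcp, pair0$rhcp)
  expect_error(synthetic_scene(cd_epsilon = 2), "cd_epsilon")
})

test_that("depth series decay exponentially in the section mean", {
  sc <- synthetic_scene(mu_atten_per_um = 0, noise = "none", dim = c(8, 8))
  z0 <- gen_depth_series(sc, n_sections = 5, z_step_um = 10)
  means <- vapply(z0$sections, mean, numeric(1))
  expect_equal(means, rep(means[1], 5))
  sc1 <- synthetic_scene(mu_atten_per_um = 0.01, noise = "none",
                         dim = c(8, 8))
  z1 <- gen_depth_series(sc1, n_sections = 9, z_step_um = 10)
  m <- vapply(z1$sections, mean, numeric(1))
  expect_equal(m[9] / m[1], exp(-0.8), tolerance = 1e-12)
  expect_error(gen_depth_series(sc1, n_sections = 2), "at least 3")
})

test_that("generators are deterministic under a fixed seed", {
  sc <- synthetic_scene(noise = "poisson", seed = 11, dim = c(16, 16))
  expect_identical(gen_pshg_stack(sc), gen_pshg_stack(sc))
  expect_identical(gen_chiral_pair(sc), gen_chiral_pair(sc))
  expect_identical(gen_depth_series(sc), gen_depth_series(sc))
  sc2 <- synthetic_scene(noise = "poisson", seed = 12, dim = c(16, 16))
  expect_false(identical(gen_pshg_stack(sc), gen_pshg_stack(sc2)))
})

test_that("Poisson noise preserves the noise-free mean", {
  base <- matrix(1000, 320, 320)  # 102400 pixels
  sc <- synthetic_scene(cd_epsilon = 0, noise = "poisson", seed = 5,
                        dim = c(320, 320))
  pair <- gen_chiral_pair(sc, base = base)
  se <- sqrt(1000 / length(base))
  expect_lt(abs(mean(pair$lhcp) - 1000), 4 * se)
  expect_lt(abs(mean(pair$rhcp) - 1000), 4 * se)
})

test_that("fiber phantom ground truth matches closed-form geometry", {
  px <- 0.5
  sc <- synthetic_scene(noise = "none", dim = c(140, 160),
                        pixel_size_um = px,
                        fiber_spec = list(list(shape = "segment",
                                               length_um = 50,
                                               width_um = 2,
                                               orientation_deg = 20)))
  ph <- gen_fiber_phantom(sc)
  expect_equal(ph$fibers$straightness, 1)
  expect_equal(ph$fibers$length_um, 50, tolerance = 0.005)
  sc2 <- synthetic_scene(noise = "none", dim = c(160, 200),
                         pixel_size_um = px,
                         fiber_spec = list(list(shape = "arc",
                                                length_um = 90,
                                                width_um = 2,
                                                orientation_deg = 0,
                                                arc_angle_deg = 180)))
  ph2 <- gen_fiber_phantom(sc2)
  expect_equal(ph2$fibers$straightness, 2 / pi, tolerance = 1e-4)
  # a fiber that cannot fit raises a placement error
  sc3 <- synthetic_scene(noise = "none", dim = c(30, 30),
                         pixel_size_um = px,
                         fiber_spec = list(list(shape = "segment",
                                                length_um = 50,
                                                width_um = 2,
                                                orientation_deg = 0)))
  expect_error(gen_fiber_phantom(sc3), "outside the image")
  expect_error(gen_fiber_phantom(synthetic_scene(noise = "none")),
               "empty")
})

test_that("rendered fiber cross-section matches the nominal width", {
  # 4 px wide horizontal fiber: stamped mask is exactly 4 px thick
  pts <- cbind(rep(20, 201), seq(10, 50, by = 0.2))
  mask <- shgmetrics:::stamp_curve(c(40, 60), pts, 4)
  thick <- colSums(mask)[15:45]
  expect_true(all(thick == 4))
})
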