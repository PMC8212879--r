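test_that("pitch angle formula matches closed forms and is monotone", {
  expect_equal(pitch_angle_from_ratio(2), 45)
  expect_equal(pitch_angle_from_ratio(1), atan(sqrt(2)) * 180 / pi,
               tolerance = 1e-12)  # 54.7356 deg
  expect_lt(pitch_angle_from_ratio(1e6), 0.1)
  b <- exp(seq(log(1e-3), log(1e3), length.out = 1e4))
  tp <- pitch_angle_from_ratio(b)
  expect_true(all(diff(tp) < 0))
  expect_true(all(tp > 0 & tp < 90))
  expect_error(pitch_angle_from_ratio(0), "positive")
  expect_error(pitch_angle_from_ratio(-2), "positive")
})

test_that("noise-free generator -> fitter round trip is exact", {
  for (b in c(1, 1.5, 2, 3)) {
    for (phi in c(0, 30, 77, 150)) {
      sc <- synthetic_scene(b_true = b, phi_deg = phi, amplitude = 100,
                            offset = 0, noise = "none", dim = c(1, 1))
      fit <- fit_pshg(gen_pshg_stack(sc))
      expect_lt(abs(fit$b_map[1] - b) / b, 1e-6)
      dphi <- if (b == 1) phi_diff_mod90(fit$phi_map[1], phi)
              else phi_diff_mod180(fit$phi_map[1], phi)
      expect_lt(dphi, 1e-6)
      expect_lt(abs(fit$amplitude_map[1] - 100) / 100, 1e-6)
      expect_lt(abs(fit$offset_map[1]), 1e-4)
      expect_gt(fit$r2_map[1], 1 - 1e-12)
    }
  }
})

test_that("fitter agrees with the exhaustive grid-search oracle", {
  set.seed(202)
  angles <- seq(0, 170, by = 10)
  for (i in 1:20) {
    b <- runif(1, 0.8, 4)
    phi <- runif(1, 0, 180)
    A <- runif(1, 50, 500)
    y <- pshg_model(angles, b, phi, A, 0)
    oracle <- grid_fit_oracle(angles, y)
    fit <- fit_pshg(pol_stack(lapply(y, function(v) matrix(v, 1, 1)),
                              angles), fit_offset = FALSE)
    expect_lt(abs(fit$b_map[1] - oracle$b), 2e-3)
    expect_lt(phi_diff_mod180(fit$phi_map[1], oracle$phi), 2e-3)
  }
})

test_that("angle-uniform responses are masked invalid", {
  st <- pol_stack(lapply(1:6, function(i) matrix(100, 2, 2)),
                  seq(0, 100, by = 20))
  fit <- fit_pshg(st)
  expect_equal(fit$n_valid, 0)
  expect_true(all(!fit$valid_mask))
  expect_warning(pm <- pitch_map(fit), "empty")
  expect_true(is.na(pm$summary[["mean"]]))
})

test_that("all pixels below threshold give an empty-mask warning", {
  sc <- synthetic_scene(amplitude = 10, noise = "none", dim = c(2, 2))
  st <- gen_pshg_stack(sc)
  expect_warning(fit <- fit_pshg(st, min_mean_intensity = 1e6),
                 "empty fit mask")
  expect_equal(fit$n_valid, 0)
})

test_that("intensity ratio at phi vs phi+90 equals b^2 when c = 0", {
  for (b in c(1.3, 2, 3)) {
    expect_equal(pshg_model(30, b, 30, 100, 0) /
                 pshg_model(120, b, 30, 100, 0), b^2, tolerance = 1e-12)
  }
  sc <- synthetic_scene(b_true = 2, phi_deg = 40, amplitude = 100,
                        offset = 0, noise = "none", dim = c(3, 3))
  st <- gen_pshg_stack(sc, angles_deg = c(0, 40, 85, 130, 175))
  expect_equal(unique(as.numeric(st$frames[[2]])) /
               pshg_model(130, 2, 40, 100, 0), 4, tolerance = 1e-12)
})

test_that("fit is rotationally equivariant in the scene orientation", {
  base_phi <- 25
  for (delta in c(0, 40, 90, 130)) {
    sc <- synthetic_scene(b_true = 1.8, phi_deg = (base_phi + delta) %% 180,
                          amplitude = 200, offset = 0, noise = "none",
                          dim = c(1, 1))
    fit <- fit_pshg(gen_pshg_stack(sc))
    expect_lt(phi_diff_mod180(fit$phi_map[1], base_phi + delta), 1e-6)
    expect_lt(abs(fit$b_map[1] - 1.8), 1e-6)
  }
})

test_that("pitch map averages valid pixels and propagates SEM", {
  b_map <- matrix(c(1, 1, 2, 2), 2, 2)
  fit <- structure(list(b_map = b_map,
                        phi_map = matrix(0, 2, 2),
                        amplitude_map = matrix(1, 2, 2),
                        offset_map = matrix(0, 2, 2),
                        r2_map = matrix(1, 2, 2),
                        valid_mask = matrix(TRUE, 2, 2),
                        angles_deg = seq(0, 170, 10), n_valid = 4L),
                   class = "pshg_fit")
  pm <- pitch_map(fit)
  expect_equal(pm$summary[["mean"]],
               (atan(sqrt(2)) * 180 / pi + 45) / 2, tolerance = 1e-10)
  # constant map: SEM 0
  fit$b_map <- matrix(2, 2, 2)
  expect_equal(pitch_map(fit)$summary[["sem"]], 0)
})

test_that("reconstructed polar response peaks at phi and is 180-periodic", {
  sc <- synthetic_scene(b_true = 2, phi_deg = 0, amplitude = 100,
                        offset = 0, noise = "none", dim = c(1, 1))
  fit <- fit_pshg(gen_pshg_stack(sc))
  r <- reconstruct_polar_response(fit, angles_deg = seq(0, 360, by = 0.5))
  expect_equal(max(r$response), 1)
  expect_equal(r$response[r$angle_deg == 0], 1)
  half <- r$response[r$angle_deg < 180]
  expect_equal(half, r$response[r$angle_deg >= 180][seq_along(half)],
               tolerance = 1e-12)
})

test_that("noisy stacks recover b and the pitch angle accurately", {
  sc <- synthetic_scene(b_true = 2, phi_deg = 30, amplitude = 1000,
                        offset = 0, noise = "poisson", seed = 42,
                        dim = c(24, 24))
  fit <- fit_pshg(gen_pshg_stack(sc))
  v <- fit$valid_mask
  expect_gt(sum(v), 0.95 * length(v))
  expect_lt(median(abs(fit$b_map[v] - 2) / 2), 0.02)
  expect_lt(median(abs(pitch_angle_from_ratio(fit$b_map[v]) - 45)), 1)
})
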