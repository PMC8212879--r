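phantom_fibers <- function(spec, dim, px = 0.5, noise = "none",
                           seed = 1, ...) {
  sc <- synthetic_scene(noise = noise, amplitude = 1000, seed = seed,
                        dim = dim, pixel_size_um = px, fiber_spec = spec)
  ph <- gen_fiber_phantom(sc)
  list(truth = ph$fibers,
       got = extract_fibers(ph$image, pixel_size_um = px, ...))
}

test_that("a straight fiber is recovered with accurate metrics", {
  r <- phantom_fibers(list(list(shape = "segment", length_um = 50,
                                width_um = 2, orientation_deg = 20)),
                      dim = c(140, 160), min_length_um = 10)
  expect_equal(nrow(r$got$fibers), 1)
  f <- r$got$fibers
  expect_gte(f$straightness, 0.99)
  expect_lt(abs(f$length_um - 50) / 50, 0.05)
  expect_lt(abs(f$width_um - 2) / 0.5, 1)  # within 1 px of truth
})

test_that("a semicircular arc recovers straightness 2/pi", {
  r <- phantom_fibers(list(list(shape = "arc", length_um = 90,
                                width_um = 2, orientation_deg = 0,
                                arc_angle_deg = 180)),
                      dim = c(160, 200), min_length_um = 10)
  expect_equal(nrow(r$got$fibers), 1)
  expect_lt(abs(r$got$fibers$straightness - 2 / pi), 0.03)
})

test_that("metrics are invariant to a 90-degree rotation", {
  r0 <- phantom_fibers(list(list(shape = "segment", length_um = 50,
                                 width_um = 2, orientation_deg = 15)),
                       dim = c(160, 160), min_length_um = 10)
  r90 <- phantom_fibers(list(list(shape = "segment", length_um = 50,
                                  width_um = 2, orientation_deg = 105)),
                        dim = c(160, 160), min_length_um = 10)
  for (m in c("length_um", "width_um", "straightness")) {
    expect_lt(abs(r0$got$fibers[[m]] - r90$got$fibers[[m]]) /
              r0$got$fibers[[m]], 0.02)
  }
})

test_that("reported metrics scale exactly with pixel size", {
  sc <- synthetic_scene(noise = "none", amplitude = 1000, dim = c(140, 160),
                        pixel_size_um = 0.5,
                        fiber_spec = list(list(shape = "segment",
                                               length_um = 50,
                                               width_um = 2,
                                               orientation_deg = 20)))
  ph <- gen_fiber_phantom(sc)
  f1 <- extract_fibers(ph$image, pixel_size_um = 0.5,
                       min_length_um = 10)$fibers
  f2 <- extract_fibers(ph$image, pixel_size_um = 1.0,
                       min_length_um = 20)$fibers
  expect_equal(f2$length_um, 2 * f1$length_um)
  expect_equal(f2$width_um, 2 * f1$width_um)
  expect_equal(f2$straightness, f1$straightness)
})

test_that("straightness never exceeds 1 and blank images yield no fibers", {
  r <- phantom_fibers(list(list(shape = "wiggle", length_um = 60,
                                width_um = 2, orientation_deg = 0,
                                straightness = 0.85)),
                      dim = c(160, 200), min_length_um = 5,
                      noise = "poisson")
  expect_true(all(r$got$fibers$straightness <= 1))
  expect_true(all(r$got$fibers$straightness > 0))
  blank <- extract_fibers(matrix(0, 64, 64))
  expect_equal(nrow(blank$fibers), 0)
  flat <- extract_fibers(matrix(5, 64, 64))
  expect_equal(nrow(flat$fibers), 0)
})

test_that("fiber summaries follow mean/SEM arithmetic", {
  df <- data.frame(length_um = c(40, 60), width_um = c(2, 4),
                   straightness = c(0.9, 1.0))
  s <- fiber_summary(df)
  expect_equal(s$mean[s$metric == "length_um"], 50)
  expect_equal(s$sem[s$metric == "length_um"], 10)
  s1 <- fiber_summary(df[1, ])
  expect_true(is.na(s1$sem[1]))
  s0 <- fiber_summary(df[0, ])
  expect_equal(unique(s0$n), 0)
  expect_true(all(is.na(s0$mean)))
})

test_that("multi-fiber phantom means are close to generator truth", {
  spec <- lapply(1:6, function(i)
    list(shape = "segment", length_um = 20 + 2 * i, width_um = 2,
         orientation_deg = 30 * i,
         center_px = c(45 + 20 * ((i - 1) %% 2), 45 + 20 * ((i - 1) %/% 2))))
  sc <- synthetic_scene(noise = "none", amplitude = 1000, dim = c(130, 130),
                        pixel_size_um = 0.5, fiber_spec = spec)
  ph <- expect_error(gen_fiber_phantom(sc), NA)
  got <- extract_fibers(ph$image, pixel_size_um = 0.5, min_length_um = 15)
  # crossing fibers fragment at junctions, but total extracted length
  # should approximate total true length
  expect_gt(sum(got$fibers$length_um), 0.7 * sum(ph$fibers$length_um))
  expect_lt(sum(got$fibers$length_um), 1.1 * sum(ph$fibers$length_um))
})
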