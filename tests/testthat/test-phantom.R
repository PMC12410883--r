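test_that("a zero-fiber population is an empty table", {
  cfg <- phantom_config(fiber_count = 0, seed = 1)
  specs <- sample_population(cfg)
  expect_equal(nrow(specs), 0L)
})

test_that("sampled axon diameters follow the configured GEV law", {
  cfg <- phantom_config(fiber_count = 10000,
                        axon_diameter_law = c(mu = 0.5, sigma = 0.15, xi = 0.1),
                        seed = 21)
  specs <- sample_population(cfg, place = FALSE)
  d <- 2 * specs$axon_radius_um
  # closed-form GEV mean and variance, typed independently
  mean_true <- 0.5 + 0.15 * (gamma(1 - 0.1) - 1) / 0.1
  var_true <- 0.15^2 * (gamma(1 - 0.2) - gamma(1 - 0.1)^2) / 0.1^2
  se <- sqrt(var_true / 10000)
  expect_lt(abs(mean(d) - mean_true), 2 * se)
})

test_that("a degenerate g-ratio law gives every fiber exactly that g-ratio", {
  cfg <- phantom_config(fiber_count = 50, canvas = c(1200, 1200),
                        g_ratio_law = c(mean = 0.54, sd = 0), seed = 22)
  specs <- sample_population(cfg)
  expect_true(all(specs$g_ratio_true == 0.54))
  # and the truth-table identity g = d / (d + 2 t) holds exactly
  g <- 2 * specs$axon_radius_um /
    (2 * specs$axon_radius_um + 2 * specs$myelin_thickness_um)
  expect_equal(g, specs$g_ratio_true, tolerance = 1e-12)
})

test_that("an orthogonally cut fiber rasterizes to the expected disks", {
  ras <- single_fiber_raster(axon_radius_um = 0.4, myelin_thickness_um = 0.2,
                             cut_angle_deg = 0)
  r_axon_px <- 0.4 / 0.01728   # ~23.1 px
  r_out_px <- 0.6 / 0.01728    # ~34.7 px
  expect_equal(sum(ras$instances$axon > 0), pi * r_axon_px^2,
               tolerance = 0.02)
  expect_equal(sum(ras$instances$myelin > 0),
               pi * (r_out_px^2 - r_axon_px^2), tolerance = 0.02)
  expect_false(any(ras$truth$clipped_flag))
})

test_that("an oblique cut leaves minor axes unchanged and doubles majors at 60 deg", {
  r0 <- single_fiber_raster(cut_angle_deg = 0)
  r60 <- single_fiber_raster(cut_angle_deg = 60, canvas = c(400L, 300L))
  f0 <- measure_fiber(1L, r0$instances)
  f60 <- measure_fiber(1L, r60$instances)
  px2 <- 2 * 0.01728
  expect_lt(abs(f60$axon_minor_um - f0$axon_minor_um), px2)
  expect_equal(f60$axon_major_um / f0$axon_major_um, 2, tolerance = 0.05)
  expect_equal(r60$truth$axon_major_true_um, 2 * r0$truth$axon_major_true_um,
               tolerance = 1e-12)
})

test_that("kissing partners touch but keep distinct instance ids", {
  cfg <- phantom_config(fiber_count = 2, canvas = c(512, 512), seed = 23,
                        degradation = degradation_params(kissing_fraction = 1))
  ph <- generate_phantom(cfg)
  expect_equal(ph$specs$kissing_partner, c(2L, 1L))
  m1 <- ph$instances$axon == 1L | ph$instances$myelin == 1L
  m2 <- ph$instances$axon == 2L | ph$instances$myelin == 2L
  expect_false(any(m1 & m2))
  grown <- EBImage::imageData(EBImage::dilate(EBImage::Image(m1 * 1),
                                              EBImage::makeBrush(3, "box"))) > 0.5
  expect_true(any(grown & m2))  # masks share a boundary
})

test_that("undegraded non-kissing phantoms have one component per fiber", {
  cfg <- phantom_config(fiber_count = 25, canvas = c(768, 768), seed = 24)
  ph <- generate_phantom(cfg)
  un <- ph$instances$axon > 0 | ph$instances$myelin > 0
  lab <- EBImage::bwlabel(EBImage::Image(un * 1))  # independent CC oracle
  expect_equal(max(lab), 25)
})

test_that("the same seed reproduces rasters and tables byte for byte", {
  cfg <- phantom_config(fiber_count = 10, canvas = c(400, 400), seed = 25,
                        degradation = degradation_params(
                          myelin_gap_probability = 0.5, gap_arc = 60,
                          boundary_noise_amplitude = 1, semantic_blur = 0.8))
  p1 <- generate_phantom(cfg)
  p2 <- generate_phantom(cfg)
  expect_identical(p1$semantic$scores, p2$semantic$scores)
  expect_identical(p1$instances, p2$instances)
  expect_identical(p1$truth, p2$truth)
})

test_that("fibers extending beyond the canvas are clipped and flagged", {
  px_um <- 17.28 / 1000
  specs <- data.frame(fiber_id = 1L, axon_radius_um = 0.4,
                      myelin_thickness_um = 0.2, cut_angle_deg = 0,
                      center_x_um = 10 * px_um, center_y_um = 100 * px_um,
                      orientation_deg = 0, kissing_partner = NA_integer_,
                      g_ratio_true = 2 / 3)
  ras <- rasterize_population(specs, c(200, 200), 17.28)
  expect_true(ras$truth$clipped_flag)
  expect_true(sum(ras$instances$axon > 0) < pi * (0.4 / px_um)^2 * 0.9)
})

test_that("an impossible placement names the achieved fiber count", {
  cfg <- phantom_config(fiber_count = 80, canvas = c(96, 96), seed = 26)
  expect_error(sample_population(cfg),
               class = "fibermorph_placement_error")
  expect_error(sample_population(cfg), "placed \\d+ of 80")
})

test_that("zero degradation is the identity", {
  cfg <- phantom_config(fiber_count = 5, canvas = c(400, 400), seed = 27)
  ph <- generate_phantom(cfg)
  expect_identical(ph$semantic$scores, ph$semantic_clean$scores)
})

test_that("a 90-degree gap removes one quarter of each myelin annulus", {
  cfg <- phantom_config(fiber_count = 8, canvas = c(700, 700), seed = 28,
                        cut_angle_law = c(min = 0, max = 45),
                        degradation = degradation_params(
                          myelin_gap_probability = 1, gap_arc = 90))
  ph <- generate_phantom(cfg)
  before <- ph$semantic_clean$scores[, , 3]
  after <- ph$semantic$scores[, , 3]
  for (id in ph$specs$fiber_id) {
    sel <- ph$instances$myelin == id
    removed <- 1 - sum(after[sel] > 0.5) / sum(before[sel] > 0.5)
    expect_equal(removed, 0.25, tolerance = 0.15)
  }
})

test_that("degraded maps remain valid semantic maps", {
  cfg <- phantom_config(fiber_count = 6, canvas = c(400, 400), seed = 29,
                        degradation = degradation_params(
                          semantic_blur = 1.5, boundary_noise_amplitude = 2,
                          myelin_gap_probability = 0.5))
  ph <- generate_phantom(cfg)
  s <- ph$semantic$scores
  sums <- s[, , 1] + s[, , 2] + s[, , 3]
  expect_lt(max(abs(sums - 1)), 1e-9)
  expect_true(all(s >= 0 & s <= 1))
  expect_gt(max(abs(ph$semantic$scores - ph$semantic_clean$scores)), 0)
})
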