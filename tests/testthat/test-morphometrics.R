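# Exhaustive caliper oracles, independent of the rotating-calipers path
feret_bruteforce <- function(poly) {
  max(stats::dist(unique(poly)))
}
minferet_scan <- function(poly, step_deg = 0.1) {
  th <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  x <- poly[, 1]; y <- poly[, 2]
  widths <- vapply(th, function(t) {
    p <- x * sin(t) + y * cos(t)
    max(p) - min(p)
  }, numeric(1))
  min(widths)
}

test_that("boundary polygon follows the marching-squares conventions", {
  # single pixel -> 4-vertex diamond of perimeter 2*sqrt(2)
  one <- matrix(0, 3, 3); one[2, 2] <- 1
  p <- boundary_polygon(one)
  expect_equal(nrow(p), 4)
  expect_equal(polygon_perimeter(p, smooth = 0), 2 * sqrt(2))
  # 10x10 filled square -> chamfered square, shoelace area 99.5 px^2
  sq <- raster_rect(10, 10)
  psq <- boundary_polygon(sq)
  expect_equal(spikemorph:::polygon_area(psq), 99.5)
  # convexity: hull area >= polygon area
  e <- boundary_polygon(raster_ellipse(30, 12, 25))
  hull <- e[grDevices::chull(e[, 1], e[, 2]), ]
  expect_gte(spikemorph:::polygon_area(hull),
             spikemorph:::polygon_area(e) - 1e-9)
  expect_error(boundary_polygon(matrix(0, 3, 3)), "foreground")
})

test_that("caliper diameters match closed forms on a rectangle", {
  # 60 x 20 px axis-aligned rectangle at 10 px/mm:
  # Feret = diagonal of the midpoint contour, MinFeret = 2.0 mm
  m <- measure_mask(raster_rect(20, 60), px_per_mm = 10)
  expect_equal(m$feret_mm, sqrt(6^2 + 2^2), tolerance = 0.02)
  expect_equal(m$minferet_mm, 2.0, tolerance = 0.02)
  expect_equal(m$area_mm2, 2 * 6, tolerance = 1e-9)
})

test_that("a disk measures equal calipers within 1.5% of its diameter", {
  m <- measure_mask(raster_disk(50), px_per_mm = 10)
  expect_equal(m$feret_mm, 10, tolerance = 0.015)
  expect_equal(m$minferet_mm, 10, tolerance = 0.015)
  expect_equal(m$area_mm2, pi * 25, tolerance = 0.01)
  expect_gte(m$circularity, 0.98)
  expect_equal(m$aspect_ratio, 1, tolerance = 0.01)
  expect_gte(m$solidity, 0.98)
})

test_that("caliper diameters are rotation invariant on an ellipse", {
  for (ang in c(0, 17, 45, 90, 133)) {
    m <- measure_mask(raster_ellipse(40, 15, theta_deg = ang),
                      px_per_mm = 10)
    expect_equal(m$feret_mm, 8.0, tolerance = 0.02)
    expect_equal(m$minferet_mm, 3.0, tolerance = 0.02)
    expect_equal(m$area_mm2, pi * 4 * 1.5, tolerance = 0.01)
  }
})

test_that("rotating calipers agree with exhaustive oracles", {
  shapes <- list(
    raster_ellipse(25, 10, 33), raster_ellipse(18, 16, 70),
    raster_rect(12, 40), raster_disk(15))
  set.seed(4)
  for (mask in shapes) {
    p <- boundary_polygon(mask)
    fer <- feret_diameters(p)
    expect_equal(fer$feret, feret_bruteforce(p), tolerance = 1e-12)
    expect_equal(fer$minferet, minferet_scan(p), tolerance = 0.005)
  }
})

test_that("moment ellipse recovers analytic axes and rotation behaviour", {
  m <- raster_ellipse(40, 15, 0)
  idx <- which(m > 0)
  ell <- fit_ellipse_moments((idx - 1) %% nrow(m) + 1,
                             (idx - 1) %/% nrow(m) + 1)
  expect_equal(ell$major, 80, tolerance = 0.02)
  expect_equal(ell$minor, 30, tolerance = 0.02)
  # the fitted ellipse has exactly the particle area
  expect_equal(pi * ell$major / 2 * ell$minor / 2, length(idx),
               tolerance = 1e-9)
  # axis-aligned with long axis vertical in raster terms -> angle 90
  expect_true(min(abs(ell$angle_deg - 90), ell$angle_deg,
                  abs(ell$angle_deg - 180)) < 2)
  # rotating the region by 90 deg swaps nothing but the angle
  ell2 <- fit_ellipse_moments((idx - 1) %/% nrow(m) + 1,
                              (idx - 1) %% nrow(m) + 1)
  expect_equal(ell2$major, ell$major, tolerance = 1e-6)
  expect_equal(ell2$minor, ell$minor, tolerance = 1e-6)
  expect_equal(min(abs(ell2$angle_deg - ell$angle_deg),
                   abs(abs(ell2$angle_deg - ell$angle_deg) - 90)), 0,
               tolerance = 2)
  # disk: major = minor within 1%
  d <- raster_disk(30)
  idd <- which(d > 0)
  elld <- fit_ellipse_moments((idd - 1) %% nrow(d) + 1,
                              (idd - 1) %/% nrow(d) + 1)
  expect_equal(elld$major / elld$minor, 1, tolerance = 0.01)
})

test_that("shape descriptors reproduce their closed forms", {
  # perfect circle, analytic inputs
  r <- 3
  d <- shape_descriptors(pi * r^2, 2 * pi * r, 2 * r, 2 * r, pi * r^2)
  expect_equal(d$circularity, 1)
  expect_equal(d$roundness, 1)
  expect_equal(d$aspect_ratio, 1)
  expect_equal(d$solidity, 1)
  # ellipse semi-axes 4 x 2 mm with Ramanujan perimeter
  A <- pi * 4 * 2
  P <- ellipse_perimeter(4, 2)
  d2 <- shape_descriptors(A, P, 8, 4, A)
  expect_equal(d2$circularity, 4 * pi * A / P^2, tolerance = 1e-12)
  expect_equal(d2$circularity, 0.841, tolerance = 0.001)
  expect_equal(d2$roundness, 0.5, tolerance = 1e-12)
  # circularity decreases monotonically with elongation
  circs <- vapply(c(2, 5, 10, 25, 60), function(L)
    shape_descriptors(L * 1, 2 * (L + 1), L, 1, L)$circularity, numeric(1))
  expect_true(all(diff(circs) < 0))
  expect_error(shape_descriptors(-1, 1, 1, 1, 1), "positive")
})

test_that("measured ellipse circularity and roundness match analytics", {
  m <- measure_mask(raster_ellipse(40, 20), px_per_mm = 10)
  A <- pi * 4 * 2
  P <- ellipse_perimeter(4, 2)
  expect_equal(m$circularity, 4 * pi * A / P^2, tolerance = 0.01)
  expect_equal(m$roundness, 0.5, tolerance = 0.02)
  expect_equal(m$aspect_ratio, 2, tolerance = 0.02)
})

test_that("full-spike measurement respects the truth at zero variance", {
  sim <- generate_spike_image(spike_sim_config(
    n_rows = 6, sd_length_mm = 0, sd_width_mm = 0, seed = 17))
  cal <- set_scale(sim$scale_bar$length_px, sim$scale_bar$length_mm)
  seg <- segment_spike(sim$image, cal)
  m <- measure_spike(seg$labeled, seg$layout, cal)
  expect_equal(nrow(m), 12)
  expect_true(all(abs(m$feret_mm - 7) / 7 < 0.02))
  expect_true(all(abs(m$minferet_mm - 3.5) / 3.5 < 0.03))
  # invariants of the record
  expect_true(all(m$feret_mm >= m$minferet_mm))
  expect_true(all(m$major_mm >= m$minor_mm))
  expect_true(all(m$circularity <= 1 & m$circularity >= 0))
  expect_true(all(abs(pi * m$major_mm / 2 * m$minor_mm / 2 - m$area_mm2)
                  / m$area_mm2 < 1e-6))
  expect_equal(m$aspect_ratio, m$major_mm / m$minor_mm)
  # feret >= major*(1-eps), minferet <= minor*(1+eps) for convex grains
  expect_true(all(m$feret_mm >= m$major_mm * 0.97))
  expect_true(all(m$minferet_mm <= m$minor_mm * 1.03))
})

test_that("mm-valued outputs are invariant to the rendering scale", {
  ms <- lapply(c(10, 20), function(ppmm) {
    sim <- generate_spike_image(spike_sim_config(
      n_rows = 4, sd_length_mm = 0, sd_width_mm = 0,
      rotation_jitter_deg = 0, px_per_mm = ppmm, seed = 23))
    cal <- set_scale(sim$scale_bar$length_px, sim$scale_bar$length_mm)
    seg <- segment_spike(sim$image, cal)
    measure_spike(seg$labeled, seg$layout, cal)
  })
  for (cl in c("area_mm2", "feret_mm", "minferet_mm", "perimeter_mm"))
    expect_equal(mean(ms[[1]][[cl]]), mean(ms[[2]][[cl]]), tolerance = 0.02)
})

test_that("degenerate single-line regions are flagged, not fatal", {
  line <- matrix(0, 5, 40); line[3, 3:38] <- 1
  p <- boundary_polygon(line)
  fer <- feret_diameters(p)
  expect_true(fer$feret > 30)
  expect_true(fer$minferet >= 1 - 1e-9)
  ell <- fit_ellipse_moments(rep(3, 36), 3:38)
  expect_true(ell$degenerate)
  expect_equal(ell$major, 36)
  # empty labelled set -> empty measurement frame
  cal <- set_scale(10, 1)
  lab <- label_particles(matrix(FALSE, 5, 5), cal)
  expect_equal(nrow(measure_spike(lab, NULL, cal)), 0)
})
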