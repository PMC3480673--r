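# CURE, E_RMS, DI, LVEF.

test_that("ring Fourier powers match the stated conventions", {
  theta <- 2 * pi * (0:29) / 30
  expect_equal(fourier_ring_power(rep(0.7, 30)), c(p0 = 0.49, p1 = 0),
               tolerance = 1e-12)
  expect_equal(fourier_ring_power(sin(theta)), c(p0 = 0, p1 = 1),
               tolerance = 1e-12)
  expect_equal(fourier_ring_power(0.3 + 0.2 * cos(theta)),
               c(p0 = 0.09, p1 = 0.04), tolerance = 1e-12)
  expect_error(fourier_ring_power(c(1, 2, 3)), "at least 4")
})

test_that("ring Fourier powers agree with the direct-summation oracle on random rings", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(c(8, 16, 30, 45), 1)
    ecc <- rnorm(n, sd = 0.2)
    p <- fourier_ring_power(ecc)
    o <- oracle_ring_power(ecc)
    expect_lt(max(abs(p - o)), 1e-10)
  }
})

test_that("CURE reproduces its boundary cases and the plug-in value", {
  uniform <- make_ring_series(c0 = 0.1, a1 = 0)
  expect_equal(cure(uniform), 1, tolerance = 1e-12)
  sinus <- make_ring_series(c0 = 0, a1 = 1)
  expect_equal(cure(sinus), 0, tolerance = 1e-12)
  # A0^2 = 2, A1^2 = 1 -> sqrt(2/4)
  expect_equal(sqrt(2 / (2 + 2 * 1)), 0.7071068, tolerance = 1e-7)
  mixed <- make_ring_series(c0 = 1, a1 = 1)
  expect_equal(cure(mixed), sqrt(1 / 3), tolerance = 1e-12)
  expect_error(cure(make_ring_series(c0 = 0, a1 = 0)), "undefined")
})

test_that("CURE is scale-free, bounded, and degrades monotonically with the first harmonic", {
  base <- make_ring_series(c0 = 0.4, a1 = 0.15, phase = 1.1)
  scaled <- base
  scaled$ecc <- scaled$ecc * 7.3
  expect_equal(cure(base), cure(scaled), tolerance = 1e-12)

  c0 <- 0.3
  amps <- c(0, 0.05, 0.1, 0.2, 0.4, 0.8)
  vals <- vapply(amps, function(a) cure(make_ring_series(c0, a)), numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_equal(vals, sqrt(c0^2 / (c0^2 + 2 * amps^2)), tolerance = 1e-10)
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("E_RMS implements the root-mean-square formula and is a metric", {
  expect_equal(e_rms(c(3, 4), c(0, 0)), sqrt(25 / 2), tolerance = 1e-12)
  expect_equal(e_rms(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(e_rms(c(1, 2, 3) + 7, c(1, 2, 3)), 7, tolerance = 1e-12)
  expect_error(e_rms(c(1, 2), c(1, 2, 3)), "different node sets")
  expect_error(e_rms(c(1, NA), c(1, 2)), "unactivated")

  set.seed(9)
  for (i in 1:20) {
    a <- rnorm(15); b <- rnorm(15); cc <- rnorm(15)
    expect_equal(e_rms(a, b), e_rms(b, a))                  # symmetry
    expect_lte(e_rms(a, cc), e_rms(a, b) + e_rms(b, cc) + 1e-12) # triangle
    expect_gte(e_rms(a, b), 0)
  }
})

test_that("dyssynchrony index is the peak-time spread with translation invariance", {
  mk <- function(tpeaks) {
    dplyr::bind_rows(lapply(seq_along(tpeaks), function(i) {
      tibble::tibble(segment = c("anterior", "lateral", "posterior", "septum")[i],
                     frame_ms = seq(0, 300, by = 10),
                     e1 = exp(-((frame_ms - tpeaks[i]) / 50)^2))
    }))
  }
  expect_equal(dyssynchrony_index(mk(c(180, 240, 240, 210))), 60)
  expect_equal(dyssynchrony_index(mk(c(150, 150, 150, 150))), 0)
  tr <- mk(c(100, 150, 120, 180))
  tr_shift <- tr; tr_shift$frame_ms <- tr_shift$frame_ms   # same grid,
  tr_shift$e1 <- mk(c(125, 175, 145, 205))$e1              # peaks shifted 25
  expect_equal(dyssynchrony_index(tr), dyssynchrony_index(tr_shift))
  flat <- mk(c(100, 150, 120, 180)); flat$e1[flat$segment == "septum"] <- 1
  expect_error(dyssynchrony_index(flat), "flat")
})

test_that("surface volumes: cube, sphere, and monotone inward deformation", {
  # 10 mm cube = 1 mL (consistent units)
  v <- rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0), c(0, 10, 0),
             c(0, 0, 10), c(10, 0, 10), c(10, 10, 10), c(0, 10, 10))
  tr <- rbind(c(1, 3, 2), c(1, 4, 3), c(5, 6, 7), c(5, 7, 8),
              c(1, 2, 6), c(1, 6, 5), c(2, 3, 7), c(2, 7, 6),
              c(3, 4, 8), c(3, 8, 7), c(4, 1, 5), c(4, 5, 8))
  expect_equal(surface_volume(v, tr) / 1000, 1, tolerance = 1e-12)

  s <- make_sphere_surface(r = 12, n_theta = 72, n_phi = 36)
  expect_equal(surface_volume(s$vertices, s$triangles), 4 * pi * 12^3 / 3,
               tolerance = 5e-3)
  expect_error(surface_volume(s$vertices, s$triangles[, c(2, 1, 3)]),
               "inverted")

  # uniform inward radial displacement strictly decreases the LV volume
  m <- test_heart()
  v0 <- cavity_volume(m)
  rad <- cbind(m$nodes[, 1], m$nodes[, 2], 0)
  rad <- rad / pmax(sqrt(rowSums(rad^2)), 1e-9)
  expect_lt(cavity_volume(m, -0.5 * rad), v0)
  expect_equal(cavity_volume(m, matrix(0, nrow(m$nodes), 3)), v0,
               tolerance = 1e-12)
})

test_that("LVEF follows its defining formula", {
  expect_equal(lvef(100, 65), 0.35, tolerance = 1e-12)
  expect_equal(lvef(80, 80), 0)
  expect_error(lvef(0, 10), "EDV")
  expect_error(lvef(50, -1), "ESV")
  esvs <- seq(10, 40, by = 5)
  expect_true(all(diff(vapply(esvs, function(e) lvef(50, e), numeric(1))) < 0))
  # contraction_frames dispatch
  fr <- test_contraction("lbbb")
  expect_equal(lvef(fr), (fr$edv_ml - fr$esv_ml) / fr$edv_ml)
})

test_that("segment traces and two-zone activation wire segments correctly", {
  m <- test_heart()
  two <- make_activation_fixture(m, "two_zone", offset = 60)
  tz <- as.numeric(two)
  sept_nodes <- unique(as.vector(m$elems[m$elem$segment == "septum", ]))
  other <- setdiff(unique(as.vector(m$elems[m$elem$segment == "lateral", ])),
                   sept_nodes)
  expect_equal(mean(tz[other]) - mean(tz[sept_nodes]), 60)

  # systolic window starts at first activation and ends at minimum volume
  fr <- test_contraction("lbbb")
  sf <- systolic_frames(fr, test_lbbb())
  expect_equal(max(sf), fr$times[which.min(fr$volume_ml)])
  expect_gte(min(sf), 0)
})
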