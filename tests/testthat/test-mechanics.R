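# Quasi-static contraction mechanics.

test_that("active stress twitch is causal, peaks at t_max, and is time-invariant", {
  tw <- twitch_params(t_max = 12, t_rise = 60, t_decay = 80, duration = 400)
  expect_equal(active_stress(c(-50, 0, 10), 20, tw), c(0, 0, 0))
  tt <- seq(0, 500, by = 0.25)
  tr <- active_stress(tt, 0, tw)
  expect_equal(max(tr), 12, tolerance = 1e-9)
  expect_equal(tr[tt >= 400], rep(0, sum(tt >= 400)))
  # shifting t_act shifts the whole trace
  expect_equal(active_stress(tt + 35, 35, tw), tr, tolerance = 1e-12)
  # continuity across the peak
  expect_lt(abs(active_stress(60 + 1e-8, 0, tw) - active_stress(60 - 1e-8, 0, tw)),
            1e-5)
})

test_that("patch test: linear displacement reproduces the exact constant strain", {
  set.seed(3)
  X <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1)) +
    matrix(runif(24, -0.12, 0.12), 8, 3)
  A <- matrix(c(0.05, 0.02, -0.01, 0.00, -0.03, 0.01, 0.02, 0.01, 0.04), 3, 3)
  U <- X %*% t(A)
  F_exact <- diag(3) + A
  E_exact <- (t(F_exact) %*% F_exact - diag(3)) / 2

  mesh <- list(nodes = X, elems = matrix(1:8, 1, 8))
  class(mesh) <- "heart_mesh"
  for (xi in list(c(0, 0, 0), c(0.3, -0.7, 0.5), c(-0.9, 0.9, -0.2))) {
    samples <- tibble::tibble(sample = 1L, theta = 0, px = 0, py = 0, pz = 0,
                              cx = 1, cy = 0, cz = 0, element = 1L,
                              xi1 = xi[1], xi2 = xi[2], xi3 = xi[3])
    st <- strain_at_samples(mesh, U, samples)
    E_fem <- matrix(c(st$e11, st$e12, st$e13,
                      st$e12, st$e22, st$e23,
                      st$e13, st$e23, st$e33), 3, 3)
    expect_lt(max(abs(E_fem - E_exact)), 1e-10)
    expect_equal(st$ecc, E_exact[1, 1], tolerance = 1e-10)
  }
})

test_that("Green-Lagrange strain is objective and matches the stretch closed form", {
  slab <- make_slab_mesh(2, 2, 2, h = 1)
  samples <- tibble::tibble(sample = 1L, theta = 0, px = 0, py = 0, pz = 0,
                            cx = 1, cy = 0, cz = 0, element = 4L,
                            xi1 = 0.2, xi2 = -0.4, xi3 = 0.6)
  # zero displacement: zero strain
  st0 <- strain_at_samples(slab, matrix(0, nrow(slab$nodes), 3), samples)
  expect_equal(st0$ecc, 0, tolerance = 1e-14)
  expect_equal(st0$e1, 0, tolerance = 1e-14)

  # rigid rotation: E = 0 to machine precision
  R <- oracle_random_rotation(5)
  U_rig <- slab$nodes %*% t(R) - slab$nodes +
    matrix(c(0.3, -0.2, 0.1), nrow(slab$nodes), 3, byrow = TRUE)
  st_r <- strain_at_samples(slab, U_rig, samples)
  expect_lt(max(abs(c(st_r$e11, st_r$e22, st_r$e33, st_r$e23, st_r$e13,
                      st_r$e12))), 1e-10)
  expect_lt(abs(st_r$e1), 1e-10)

  # uniform stretch 1.1 along the circumferential direction
  U_st <- cbind(0.1 * slab$nodes[, 1], 0, 0)
  st_s <- strain_at_samples(slab, U_st, samples)
  expect_equal(st_s$ecc, (1.1^2 - 1) / 2, tolerance = 1e-12)
  expect_equal(st_s$e1, 0.105, tolerance = 1e-12)
})

test_that("sparse assembly equals dense brute-force assembly on a small mesh", {
  slab <- make_slab_mesh(2, 2, 1, h = c(1.3, 0.9, 1.1), fiber = c(1, 1, 0) / sqrt(2))
  sys <- assemble_global(slab, material_params(), base_spring = 0)
  n <- nrow(slab$nodes)
  Kd <- matrix(0, 3 * n, 3 * n)
  R <- crtsim:::.fiber_frame(slab$fiber[1, ])
  Cg <- oracle_rotate_elasticity(material_params()$C, R)
  for (e in seq_len(nrow(slab$elems))) {
    conn <- slab$elems[e, ]
    Ke <- oracle_element_stiffness(slab$nodes[conn, , drop = FALSE], Cg, n = 2)
    dofs <- as.vector(t(cbind(3 * conn - 2, 3 * conn - 1, 3 * conn)))
    Kd[dofs, dofs] <- Kd[dofs, dofs] + Ke
  }
  expect_lt(max(abs(as.matrix(sys$K) - Kd)), 1e-10 * max(abs(Kd)))
  # two disconnected elements assemble block-diagonally
  two <- make_slab_mesh(1, 1, 1)
  two$nodes <- rbind(two$nodes, two$nodes + 10)
  two$elems <- rbind(two$elems, two$elems + 8L)
  two$fiber <- rbind(two$fiber, two$fiber)
  sys2 <- assemble_global(two, material_params(), base_spring = 0)
  K2 <- as.matrix(sys2$K)
  expect_equal(max(abs(K2[1:24, 25:48])), 0)
  expect_equal(K2[1:24, 1:24], K2[25:48, 25:48], tolerance = 1e-12)
})

test_that("constrained heart system is positive definite and solves accurately", {
  sys <- test_mech_sys()
  m <- test_heart()
  # solve a frame and verify the residual contract and energy consistency
  map <- make_activation_fixture(m, "uniform", t0 = 0)
  tw <- twitch_params()
  d <- solve_frame(m, sys, map, tw, t = 60)
  dv <- as.vector(t(d))
  # rebuild the force for the residual check
  F <- numeric(length(dv))
  t_act <- rep(0, nrow(m$nodes))
  sig <- active_stress(60, 0, tw)
  for (e in seq_len(nrow(m$elems))) {
    conn <- m$elems[e, ]
    dofs <- as.vector(t(cbind(3 * conn - 2, 3 * conn - 1, 3 * conn)))
    F[dofs] <- F[dofs] + sig * sys$g_unit[, e]
  }
  res <- sqrt(sum((as.numeric(sys$K %*% dv) - F)^2)) / sqrt(sum(F^2))
  expect_lt(res, 1e-8)
  expect_equal(sum(dv * as.numeric(sys$K %*% dv)), sum(dv * F),
               tolerance = 1e-8)
  # a frame before the earliest activation is exactly zero
  d0 <- solve_frame(m, sys, make_activation_fixture(m, "uniform", t0 = 50),
                    tw, t = 20)
  expect_equal(max(abs(d0)), 0)
})

test_that("midwall ring samples are equiangular with tangential directions", {
  m <- test_heart()
  rs <- midwall_ring_samples(m, layer = 7, n_points = 30)
  expect_equal(nrow(rs), 30)
  gaps <- diff(rs$theta)
  expect_true(all(abs(gaps - 2 * pi / 30) < 1e-9))
  # circumferential vector is orthogonal to the in-plane radial direction
  rad <- cbind(rs$px, rs$py, 0)
  rad <- rad / sqrt(rowSums(rad^2))
  dots <- rowSums(rad * cbind(rs$cx, rs$cy, rs$cz))
  expect_lt(max(abs(dots)), 1e-9)
  # the located points are reproduced by the element-local coordinates
  for (i in c(1, 11, 23)) {
    conn <- m$elems[rs$element[i], ]
    X <- m$nodes[conn, , drop = FALSE]
    N <- crtsim:::hex_shape(c(rs$xi1[i], rs$xi2[i], rs$xi3[i]))
    p <- drop(crossprod(N, X))
    expect_lt(sqrt(sum((p - c(rs$px[i], rs$py[i], rs$pz[i]))^2)), 1e-6)
  }
  expect_error(midwall_ring_samples(m, layer = 99), "layer")
})

test_that("synchronous activation contracts near-uniformly; LBBB contracts septum first", {
  m <- test_heart()
  sys <- test_mech_sys()
  tw <- twitch_params()
  uni <- make_activation_fixture(m, "uniform", t0 = 0)
  d <- solve_frame(m, sys, uni, tw, t = 60)
  rs <- strain_at_samples(m, d, midwall_ring_samples(m, 7, 30))
  # free-wall samples (away from the RV attachment) are near-uniform
  free <- rs$ecc[segment_of_angle(rs$theta) != "septum"]
  expect_lt(stats::sd(free) / abs(mean(free)), 0.1)
  expect_true(all(rs$ecc < 0))             # circumferential shortening

  # LBBB: time-to-peak strain at septal samples precedes lateral samples
  fr <- test_contraction("lbbb")
  series <- ring_strain_series(m, fr, layers = 7, n_points = 30)
  tr <- segment_strain_traces(series, layer = 7)
  peaks <- attr(tr, "peaks")
  expect_lt(peaks$t_peak[peaks$segment == "septum"],
            peaks$t_peak[peaks$segment == "lateral"])
})

test_that("contraction frames reduce cavity volume and recover", {
  fr <- test_contraction("lbbb")
  expect_equal(fr$edv_ml, fr$volume_ml[1])
  expect_lt(fr$esv_ml, fr$edv_ml)
  expect_gt(min(fr$volume_ml), 0)
  # end-systole is an interior frame (the twitch releases afterwards)
  i_es <- which.min(fr$volume_ml)
  expect_gt(i_es, 1)
  expect_lt(i_es, length(fr$times))
})
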