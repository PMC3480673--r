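# Monodomain solver and activation protocols.

test_that("resting state is a fixed point of the kinetics and of the solver", {
  p <- monodomain_params()
  st <- list(v = rep(0, 5), w = rep(0, 5))
  out <- reaction_step(st, 0.5, p)
  expect_equal(out$v, st$v, tolerance = 1e-9)
  expect_equal(out$w, st$w, tolerance = 1e-9)

  slab <- make_slab_mesh(4, 2, 2, h = 2)
  vs <- run_monodomain(slab, monodomain_params(t_end = 50), list())
  expect_lt(max(abs(vs$frames)), 1e-6)
})

test_that("a suprathreshold cell fires an action potential matching a reference integrator", {
  skip_if_not_installed("deSolve")
  p <- monodomain_params()
  # reference: high-accuracy LSODA integration of the same two-variable ODEs
  rhs <- function(t, y, parms) {
    u <- y[1]; w <- y[2]
    du <- (p$ap_k * u * (u - p$ap_a) * (1 - u) - u * w) / p$tau_ms
    eps <- p$ap_eps0 + p$ap_mu1 * w / (u + p$ap_mu2)
    dw <- eps * (-w - p$ap_k * u * (u - p$ap_a - 1)) / p$tau_ms
    list(c(du, dw))
  }
  times <- seq(0, 400, by = 1)
  ref <- deSolve::ode(c(0.3, 0), times, rhs, NULL, rtol = 1e-10, atol = 1e-12)

  st <- list(v = 0.3, w = 0)
  dt <- 0.01
  tr <- numeric(length(times)); tr[1] <- 0.3
  for (i in 2:length(times)) {
    for (s in seq_len(round(diff(times)[1] / dt)))
      st <- reaction_step(st, dt, p)
    tr[i] <- st$v
  }
  expect_lt(max(abs(tr - ref[, 2])), 5e-3)
  # action-potential shape: upstroke to ~1 then return toward rest
  expect_gt(max(tr), 0.95)
  expect_lt(tr[length(tr)], 0.15)
  # refractory period: recovery variable keeps the cell inexcitable for
  # well over 150 ms after the upstroke
  i150 <- which(times == 150)
  expect_gt(tr[i150], 0.5)

  # determinism: identical nodes, identical trajectories
  st2 <- reaction_step(list(v = c(0.3, 0.3), w = c(0, 0)), 0.1, p)
  expect_identical(st2$v[1], st2$v[2])
})

test_that("diffusion tensor has the prescribed spectral form and scaling", {
  p <- monodomain_params(d_long = 4, d_trans = 1, beta = 2, k_ratio = 3)
  scale <- (1 / 2) * 3 / 4
  D <- diffusion_tensor(c(1, 0, 0), p)
  expect_equal(sort(eigen(D, symmetric = TRUE)$values),
               scale * c(1, 1, 4), tolerance = 1e-12)
  # isotropic when d_long = d_trans
  p_iso <- monodomain_params(d_long = 2, d_trans = 2)
  D_iso <- diffusion_tensor(c(1, 2, 2) / 3, p_iso)
  expect_equal(D_iso, diag(3) * 2 * 0.5, tolerance = 1e-12)
  # SPD for arbitrary fiber, and fast-shell scaling is multiplicative
  f <- c(1, -1, 2) / sqrt(6)
  D1 <- diffusion_tensor(f, p)
  expect_equal(D1, t(D1), tolerance = 1e-14)
  expect_gt(min(eigen(D1, symmetric = TRUE)$values), 0)
  expect_equal(diffusion_tensor(f, p, fast_scale = 6), 6 * D1,
               tolerance = 1e-14)
})

test_that("one operator-split step equals a dense reference update on a small slab", {
  slab <- make_slab_mesh(3, 2, 2, h = 1.5)          # 48 nodes
  n <- nrow(slab$nodes)
  p <- monodomain_params(dt = 0.1, t_end = 0.1, frame_every = 1)

  # independent dense assembly with the oracle shape machinery
  Dm <- diffusion_tensor(slab$fiber[1, ], p)
  gl <- oracle_gauss_1d(2)
  Kd <- matrix(0, n, n); Md <- numeric(n)
  for (e in seq_len(nrow(slab$elems))) {
    conn <- slab$elems[e, ]
    X <- slab$nodes[conn, , drop = FALSE]
    for (a in 1:2) for (b in 1:2) for (cc in 1:2) {
      xi <- c(gl$x[a], gl$x[b], gl$x[cc])
      w <- gl$w[a] * gl$w[b] * gl$w[cc]
      dN <- oracle_shape_grad(xi)
      J <- t(X) %*% dN
      dNdx <- dN %*% solve(J)
      Kd[conn, conn] <- Kd[conn, conn] + w * det(J) * dNdx %*% Dm %*% t(dNdx)
      Md[conn] <- Md[conn] + w * det(J) * oracle_shape(xi)
    }
  }
  # initial condition: a localized bump, advanced one split step by hand
  u0 <- rep(0, n); u0[1:4] <- 0.8
  w0 <- rep(0, n)
  kfun <- function(u, w) {
    du <- p$ap_k * u * (u - p$ap_a) * (1 - u) - u * w
    eps <- p$ap_eps0 + p$ap_mu1 * w / (u + p$ap_mu2)
    dw <- eps * (-w - p$ap_k * u * (u - p$ap_a - 1))
    list(du = du / p$tau_ms, dw = dw / p$tau_ms)
  }
  kk <- kfun(u0, w0)
  u_star <- u0 + p$dt * kk$du
  u_ref <- solve(diag(Md) + p$dt * Kd, Md * u_star)

  # the package path needs the same initial condition: emulate it with a
  # 1-step run whose stimulus recreates u0 exactly is impractical, so call
  # the internal update pieces directly
  sys <- crtsim:::assemble_monodomain(slab, p)
  A <- Matrix::Diagonal(x = sys$mass) + p$dt * sys$K
  stt <- reaction_step(list(v = u0, w = w0), p$dt, p)
  u_pkg <- as.numeric(Matrix::solve(Matrix::Cholesky(Matrix::forceSymmetric(A),
                                                     LDL = FALSE),
                                    sys$mass * stt$v))
  expect_lt(max(abs(u_pkg - u_ref)), 1e-8)
})

test_that("activation spreads causally and faster along than across the fiber", {
  p <- monodomain_params(t_end = 120)
  slab <- make_slab_mesh(30, 1, 1, h = 1.5)
  st <- stimulus(which(slab$nodes[, 1] < 3.1))
  am <- as.numeric(extract_activation_times(run_monodomain(slab, p, st)))
  x <- slab$nodes[, 1]
  ord <- order(x)
  expect_true(all(diff(am[ord][x[ord] > 3.1]) > -1e-9))
  expect_true(all(am >= 0, na.rm = TRUE))

  # cross-fiber slab: same geometry, fiber perpendicular to propagation
  slab_t <- make_slab_mesh(30, 1, 1, h = 1.5, fiber = c(0, 1, 0))
  p_t <- monodomain_params(t_end = 180)
  st_wide <- stimulus(which(slab_t$nodes[, 1] < 6.1))
  am_t <- as.numeric(extract_activation_times(run_monodomain(slab_t, p_t, st_wide)))
  far <- which(x > 30 & x < 40)
  expect_false(anyNA(am_t[far]))
  expect_gt(mean(am_t[far]), mean(am[far]))
})

test_that("planar conduction velocity converges under grid refinement", {
  measure_cv <- function(h) {
    p <- monodomain_params(t_end = 130)
    slab <- make_slab_mesh(round(45 / h), 1, 1, h = h)
    st <- stimulus(which(slab$nodes[, 1] < 3.01))
    am <- as.numeric(extract_activation_times(run_monodomain(slab, p, st)))
    x <- slab$nodes[, 1]
    ok <- !is.na(am) & x > 12 & x < 36
    unname(1 / coef(lm(am[ok] ~ x[ok]))[2])
  }
  cv2 <- measure_cv(1.5)
  cv_ref <- measure_cv(0.375)              # 4x refined reference
  expect_lt(abs(cv2 - cv_ref) / cv_ref, 0.05)
  # the default calibration targets ~0.6 m/s along the fiber
  expect_gt(cv_ref, 0.45)
  expect_lt(cv_ref, 0.75)
})

test_that("activation-time extraction interpolates threshold crossings linearly", {
  fake <- structure(list(times = c(0, 10, 20),
                         frames = rbind(c(0, 0.5, 1),      # crossing at a frame
                                        c(0.4, 0.6, 1),    # symmetric bracket
                                        c(0, 0, 0)),       # never crosses
                         threshold = 0.5), class = "vm_series")
  am <- extract_activation_times(fake)
  expect_equal(as.numeric(am)[1], 10)
  expect_equal(as.numeric(am)[2], 5)       # midpoint of the frame interval
  expect_true(is.na(as.numeric(am)[3]))
  expect_equal(sum(is.na(am)), 1)
})

test_that("sinus reference is reproducible and faster than LBBB", {
  sn <- as.numeric(test_sinus())
  lb <- as.numeric(test_lbbb())
  expect_false(anyNA(sn))
  expect_false(anyNA(lb))
  expect_lt(max(sn), max(lb))
  # repeated call gives the identical map
  sn2 <- as.numeric(sinus_reference(test_heart(), test_eparams()))
  expect_identical(sn, sn2)
})

test_that("LBBB map shows the left-bundle-block signature", {
  m <- test_heart()
  lb <- as.numeric(test_lbbb())
  seg_nodes <- function(seg) {
    unique(as.vector(m$elems[m$elem$segment == seg & m$elem$region == "lv", ]))
  }
  expect_gt(mean(lb[seg_nodes("lateral")]), mean(lb[seg_nodes("septum")]))
  # latest-activated element lies in the LV free wall
  emean <- vapply(seq_len(nrow(m$elems)), function(e) mean(lb[m$elems[e, ]]),
                  numeric(1))
  expect_true(m$elem$segment[which.max(emean)] %in% c("lateral", "posterior"))
  expect_true(all(lb >= 0))
  # desk-scale calibration puts the latest depolarization near 100 ms
  expect_gt(max(lb), 70)
  expect_lt(max(lb), 140)
})

test_that("VVD sign convention and refractory pre-emption behave as programmed", {
  s <- test_sites()
  lvn <- s$node_id[s$name == "LAT-E"]; rvn <- s$node_id[s$name == "RVA"]
  m <- test_heart()

  # vvd = +60: LV capture region activates immediately, RV lead region does
  # not re-fire at t = 60 (already refractory)
  p60 <- as.numeric(test_paced(60))
  expect_lt(p60[lvn], 2)

  # an RV stimulus that is fully pre-empted leaves the map essentially
  # identical to the LV-only protocol
  p60_noRV <- as.numeric(test_paced(60, rv_enabled = FALSE))
  expect_lt(mean(abs(p60 - p60_noRV)), 0.5)
  expect_gt(cor(p60, p60_noRV), 0.999)

  # vvd = 0 fires both at t = 0
  p0 <- as.numeric(test_paced(0))
  expect_lt(p0[lvn], 2)
  expect_lt(p0[rvn], 2)
})
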