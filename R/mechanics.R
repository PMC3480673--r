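# Quasi-static finite-element contraction.
#
# The solve is linear in the displacements ([K]{d} = {Ff}) with a
# transversely isotropic elasticity matrix rotated into each element's
# fiber frame; the Green-Lagrange strain is computed as a finite-strain
# post-process from the deformation gradient. Activation-time-triggered
# active fiber stress supplies the load vector frame by frame.

#' Transversely isotropic passive material parameters
#'
#' Fiber axis = 3rd material axis (so a uniaxial active fiber stress is
#' Voigt \{0,0,sigma,0,0,0\}). The 6x6 elasticity matrix is built from the
#' compliance form and verified symmetric positive definite.
#'
#' @param e_fiber Young modulus along the fiber (kPa).
#' @param e_cross Young modulus across the fiber (kPa).
#' @param nu_p in-plane (cross-fiber) Poisson ratio.
#' @param nu_fp fiber-to-cross-fiber Poisson ratio.
#' @param g_fiber fiber-plane shear modulus (kPa).
#' @return object of class `material_params` containing the 6x6 matrix `C`
#'   (kPa) in material axes.
#' @export
material_params <- function(e_fiber = 60, e_cross = 20,
                            nu_p = 0.45, nu_fp = 0.3, g_fiber = 10) {
  stopifnot(e_fiber > 0, e_cross > 0, g_fiber > 0)
  S <- matrix(0, 6, 6)
  S[1, 1] <- S[2, 2] <- 1 / e_cross
  S[3, 3] <- 1 / e_fiber
  S[1, 2] <- S[2, 1] <- -nu_p / e_cross
  S[1, 3] <- S[3, 1] <- S[2, 3] <- S[3, 2] <- -nu_fp / e_fiber
  S[4, 4] <- S[5, 5] <- 1 / g_fiber
  S[6, 6] <- 2 * (1 + nu_p) / e_cross
  C <- solve(S)
  C <- (C + t(C)) / 2
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("material parameters give a non-positive-definite elasticity matrix")
  structure(list(C = C, e_fiber = e_fiber, e_cross = e_cross,
                 nu_p = nu_p, nu_fp = nu_fp, g_fiber = g_fiber),
            class = "material_params")
}

#' Active twitch parameters
#'
#' The element twitch is zero before its activation time, rises as
#' sin^2(pi s / (2 t_rise)) to the peak `t_max` at s = t_rise, decays
#' exponentially with time constant `t_decay` under a smooth taper, and is
#' exactly zero again after `duration` ms.
#'
#' @param t_max peak active fiber stress (kPa).
#' @param t_rise rise time (ms).
#' @param t_decay decay time constant (ms).
#' @param duration total twitch duration (ms).
#' @return object of class `twitch_params`.
#' @export
twitch_params <- function(t_max = 10, t_rise = 60, t_decay = 80,
                          duration = 400) {
  stopifnot(t_max > 0, t_rise > 0, t_decay > 0, duration > t_rise)
  structure(list(t_max = t_max, t_rise = t_rise, t_decay = t_decay,
                 duration = duration), class = "twitch_params")
}

#' Active fiber stress at time t for a given activation time
#'
#' @param t time (ms); vectorized.
#' @param t_act activation (depolarization) time of the element (ms).
#' @param twitch [twitch_params()].
#' @return active stress (kPa), 0 for `t < t_act` and after the twitch.
#' @export
active_stress <- function(t, t_act, twitch) {
  s <- t - t_act
  out <- numeric(length(s))
  rising <- s >= 0 & s <= twitch$t_rise
  out[rising] <- twitch$t_max * sin(pi * s[rising] / (2 * twitch$t_rise))^2
  falling <- s > twitch$t_rise & s < twitch$duration
  if (any(falling)) {
    sf <- s[falling] - twitch$t_rise
    taper <- 1 - (sf / (twitch$duration - twitch$t_rise))^2
    out[falling] <- twitch$t_max * exp(-sf / twitch$t_decay) * taper
  }
  out
}

# orthonormal frame with the element fiber as 3rd axis; the sheet axis is
# chosen in the plane orthogonal to the fiber, seeded from the local radial
# (or any non-parallel) direction.
.fiber_frame <- function(fiber) {
  f <- fiber / sqrt(sum(fiber^2))
  seed <- if (abs(f[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  s <- seed - sum(seed * f) * f
  s <- s / sqrt(sum(s^2))
  n <- c(f[2] * s[3] - f[3] * s[2], f[3] * s[1] - f[1] * s[3],
         f[1] * s[2] - f[2] * s[1])   # n = f x s, right-handed (s, n, f)
  rbind(s, n, f)
}

#' Assemble the global stiffness matrix for a mesh
#'
#' Sums rotated element stiffness matrices over all hexahedra
#' (K = sum_e K_e) into a sparse symmetric matrix over 3 x n_nodes degrees
#' of freedom, then adds elastic basal restraint springs to the diagonal
#' entries of all basal-ring node dofs, which makes the constrained system
#' positive definite.
#'
#' @param mesh a `heart_mesh` with fibers.
#' @param material [material_params()].
#' @param base_spring spring constant (kPa mm) applied to each basal node
#'   dof; 0 disables the restraint.
#' @return list with sparse `K` (dsCMatrix), the Cholesky factor `chol`,
#'   per-element unit active-force vectors `g_unit` (24 x m), and bookkeeping.
#' @export
assemble_global <- function(mesh, material = material_params(),
                            base_spring = 50) {
  m <- nrow(mesh$elems)
  n <- nrow(mesh$nodes)
  quad <- hex_quadrature(2)
  ii <- vector("list", m); jj <- vector("list", m); xx <- vector("list", m)
  g_unit <- matrix(0, 24, m)
  for (e in seq_len(m)) {
    conn <- mesh$elems[e, ]
    X <- mesh$nodes[conn, , drop = FALSE]
    R <- .fiber_frame(mesh$fiber[e, ])
    C_glob <- rotate_elasticity(material$C, R)
    Ke <- element_stiffness(X, C_glob, quad)
    g_unit[, e] <- element_active_force(X, 1, mesh$fiber[e, ], quad)
    dofs <- as.vector(t(cbind(3 * conn - 2, 3 * conn - 1, 3 * conn)))
    ii[[e]] <- rep(dofs, times = 24)
    jj[[e]] <- rep(dofs, each = 24)
    xx[[e]] <- as.vector(Ke)
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(3 * n, 3 * n))
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
  base_nodes <- integer(0)
  if (base_spring > 0 && !is.null(mesh$surfaces$base)) {
    base_nodes <- unique(as.vector(mesh$surfaces$base))
    dofs <- as.vector(rbind(3 * base_nodes - 2, 3 * base_nodes - 1, 3 * base_nodes))
    K <- K + Matrix::sparseMatrix(i = dofs, j = dofs, x = base_spring,
                                  dims = dim(K))
  }
  ch <- NULL
  if (length(base_nodes) > 0) {
    ch <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(K), LDL = FALSE),
                   error = function(e) NULL)
    if (is.null(ch))
      stop("constrained global stiffness is singular; add a basal restraint")
  }
  list(K = K, chol = ch, g_unit = g_unit, base_nodes = base_nodes,
       material = material, base_spring = base_spring)
}

#' Solve one quasi-static frame
#'
#' Builds the active-force vector at time `t` (element activation time =
#' mean of its nodes' activation times; unactivated elements exert no
#' stress) and solves [K]\{d\} = \{Ff\} with the pre-factored stiffness.
#'
#' @param mesh a `heart_mesh`.
#' @param sys assembled system from [assemble_global()].
#' @param activation an `activation_map` (per-node times, ms).
#' @param twitch [twitch_params()].
#' @param t frame time (ms).
#' @return displacement field: n_nodes x 3 matrix (mm).
#' @export
solve_frame <- function(mesh, sys, activation, twitch, t) {
  n <- nrow(mesh$nodes)
  t_act <- unclass(activation)
  elem_tact <- rowMeans(matrix(t_act[mesh$elems], ncol = 8))
  sig <- ifelse(is.na(elem_tact), 0, active_stress(t, elem_tact, twitch))
  F <- numeric(3 * n)
  active <- which(sig != 0)
  for (e in active) {
    conn <- mesh$elems[e, ]
    dofs <- as.vector(t(cbind(3 * conn - 2, 3 * conn - 1, 3 * conn)))
    F[dofs] <- F[dofs] + sig[e] * sys$g_unit[, e]
  }
  if (length(active) == 0) return(matrix(0, n, 3))
  d <- if (is.null(sys$chol)) as.numeric(Matrix::solve(sys$K, F))
       else as.numeric(Matrix::solve(sys$chol, F))
  res <- sqrt(sum((as.numeric(sys$K %*% d) - F)^2)) / sqrt(sum(F^2))
  if (!is.finite(res) || res > 1e-8) {
    d <- as.numeric(Matrix::solve(sys$K, F))
  }
  matrix(d, n, 3, byrow = TRUE)
}

#' Simulate a full contraction (all mechanics frames)
#'
#' Solves the quasi-static problem every `frame_ms` over `[0, t_end]` and
#' records displacement fields and the deformed LV cavity volume per frame.
#'
#' @param mesh a `heart_mesh`.
#' @param activation an `activation_map`.
#' @param material [material_params()].
#' @param twitch [twitch_params()].
#' @param frame_ms frame interval (ms), default 10.
#' @param t_end last frame (ms), default 400 (one systolic interval).
#' @param base_spring basal restraint spring constant (kPa mm).
#' @param sys optional pre-assembled system from [assemble_global()].
#' @return object of class `contraction_frames`: list with `times`,
#'   `displacements` (list of n x 3 matrices), `volume_ml` per frame, and
#'   `edv_ml`/`esv_ml`.
#' @export
simulate_contraction <- function(mesh, activation,
                                 material = material_params(),
                                 twitch = twitch_params(),
                                 frame_ms = 10, t_end = 400,
                                 base_spring = 50, sys = NULL) {
  if (is.null(sys)) sys <- assemble_global(mesh, material, base_spring)
  times <- seq(0, t_end, by = frame_ms)
  disp <- vector("list", length(times))
  vol <- numeric(length(times))
  for (i in seq_along(times)) {
    disp[[i]] <- solve_frame(mesh, sys, activation, twitch, times[i])
    vol[i] <- cavity_volume(mesh, disp[[i]])
  }
  structure(list(times = times, displacements = disp, volume_ml = vol,
                 edv_ml = vol[1], esv_ml = min(vol)),
            class = "contraction_frames")
}

#' @export
print.contraction_frames <- function(x, ...) {
  cat("<contraction_frames> ", length(x$times), " frames, ",
      sprintf("EDV %.1f mL, ESV %.1f mL (LVEF %.1f%%)\n", x$edv_ml, x$esv_ml,
              100 * (x$edv_ml - x$esv_ml) / x$edv_ml), sep = "")
  invisible(x)
}

# ---- strain sampling ------------------------------------------------------

# invert the trilinear map for point p in element with node coords X;
# returns local coordinates (possibly slightly outside [-1,1] for points on
# a face shared with a neighbour).
.invert_trilinear <- function(X, p, tol = 1e-12, maxit = 30) {
  xi <- c(0, 0, 0)
  for (it in seq_len(maxit)) {
    N <- hex_shape(xi)
    r <- drop(crossprod(N, X)) - p
    if (sum(r^2) < tol) break
    J <- crossprod(X, hex_shape_deriv(xi))
    xi <- xi - drop(solve(J, r))
  }
  xi
}

#' Mid-wall circumferential sample points on one short-axis ring
#'
#' Places `n_points` equiangular mid-wall sample points around the LV +
#' septum ring of the given layer (ordered by circumferential angle), each
#' with its local circumferential unit vector, and resolves the containing
#' element and local coordinates for strain evaluation.
#'
#' @param mesh a `heart_mesh` built by [build_biventricular_mesh()].
#' @param layer layer index (1 = apex).
#' @param n_points samples per ring (default 30).
#' @return tibble with `sample`, `theta`, `point` columns (`px,py,pz`),
#'   circumferential direction (`cx,cy,cz`), `element`, and local
#'   coordinates `xi1,xi2,xi3`.
#' @export
midwall_ring_samples <- function(mesh, layer, n_points = 30) {
  g <- mesh$geom
  if (is.null(g$spec)) stop("midwall samples need a heart mesh, not a slab")
  spec <- g$spec
  if (layer < 1 || layer > spec$n_layers) stop("layer out of range")
  if (n_points < 4) stop("n_points must be >= 4")
  lv <- which(mesh$elem$region == "lv" & mesh$elem$layer == layer)
  if (length(lv) == 0) stop("layer has no LV elements")
  nc <- spec$n_circumferential
  nt <- spec$n_transmural
  dth <- 2 * pi / nc
  phi_mid <- mean(g$phi[c(layer, layer + 1)])
  k_mid <- min(nt - 1, floor(0.5 * nt))      # transmural element bin at depth .5
  out <- vector("list", n_points)
  for (s in seq_len(n_points)) {
    th <- 2 * pi * (s - 1) / n_points
    p <- drop(.wall_pt(th, phi_mid, 0.5, spec))
    i_bin <- floor(th / dth) %% nc
    e <- which(mesh$elem$region == "lv" & mesh$elem$itheta == i_bin &
                 mesh$elem$ilong == layer - 1 & mesh$elem$itrans == k_mid)
    X <- mesh$nodes[mesh$elems[e, ], , drop = FALSE]
    xi <- .invert_trilinear(X, p)
    out[[s]] <- tibble::tibble(
      sample = s, theta = th,
      px = p[1], py = p[2], pz = p[3],
      cx = -sin(th), cy = cos(th), cz = 0,
      element = e, xi1 = xi[1], xi2 = xi[2], xi3 = xi[3])
  }
  dplyr::bind_rows(out)
}

#' Green-Lagrange strain at sample points
#'
#' For each sample, the deformation gradient F = I + grad(u) is evaluated
#' from the trilinear shape-function gradients at the sample's local
#' coordinates, then E = (F^T F - I)/2, the circumferential component
#' eps_cc = c^T E c, and the maximum principal strain E1 (largest
#' eigenvalue of E).
#'
#' @param mesh a `heart_mesh`.
#' @param displacement n_nodes x 3 matrix (mm).
#' @param samples tibble from [midwall_ring_samples()] (or any tibble with
#'   `element`, `xi1..3`, `cx..cz` columns).
#' @return the `samples` tibble with added columns `ecc`, `e1` and the full
#'   tensor components `e11,e22,e33,e23,e13,e12`.
#' @export
strain_at_samples <- function(mesh, displacement, samples) {
  n <- nrow(samples)
  ecc <- numeric(n); e1 <- numeric(n)
  comps <- matrix(0, n, 6)
  for (s in seq_len(n)) {
    e <- samples$element[s]
    conn <- mesh$elems[e, ]
    X <- mesh$nodes[conn, , drop = FALSE]
    U <- displacement[conn, , drop = FALSE]
    xi <- c(samples$xi1[s], samples$xi2[s], samples$xi3[s])
    gr <- hex_grad_global(X, xi)
    G <- crossprod(U, gr$dNdx)          # grad u, G[i,j] = du_i/dx_j
    F <- diag(3) + G
    E <- (crossprod(F) - diag(3)) / 2
    cvec <- c(samples$cx[s], samples$cy[s], samples$cz[s])
    ecc[s] <- drop(cvec %*% E %*% cvec)
    e1[s] <- max(eigen(E, symmetric = TRUE, only.values = TRUE)$values)
    comps[s, ] <- c(E[1, 1], E[2, 2], E[3, 3], E[2, 3], E[1, 3], E[1, 2])
  }
  out <- samples
  out$ecc <- ecc; out$e1 <- e1
  out$e11 <- comps[, 1]; out$e22 <- comps[, 2]; out$e33 <- comps[, 3]
  out$e23 <- comps[, 4]; out$e13 <- comps[, 5]; out$e12 <- comps[, 6]
  out
}

#' Circumferential ring-strain series over the equatorial slices
#'
#' Evaluates eps_cc (and E1) at `n_points` mid-wall samples on each of the
#' requested layers for every mechanics frame — the input of the CURE and
#' segment-trace indices.
#'
#' @param mesh a `heart_mesh`.
#' @param frames a `contraction_frames` object.
#' @param layers short-axis slices to sample (default 6:9, near the equator).
#' @param n_points circumferential samples per ring (default 30).
#' @return tibble with `slice`, `frame_ms`, `sample`, `theta`, `ecc`, `e1`.
#' @export
ring_strain_series <- function(mesh, frames, layers = 6:9, n_points = 30) {
  samp <- lapply(layers, function(l) midwall_ring_samples(mesh, l, n_points))
  out <- vector("list", length(frames$times) * length(layers))
  k <- 0
  for (fi in seq_along(frames$times)) {
    for (li in seq_along(layers)) {
      k <- k + 1
      st <- strain_at_samples(mesh, frames$displacements[[fi]], samp[[li]])
      out[[k]] <- tibble::tibble(
        slice = layers[li], frame_ms = frames$times[fi],
        sample = st$sample, theta = st$theta, ecc = st$ecc, e1 = st$e1)
    }
  }
  dplyr::bind_rows(out)
}
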