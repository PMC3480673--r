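# Synthetic fixtures: micro-meshes and analytic strain/activation fields
# that make every pipeline stage testable without the full heart model.

#' Regular hexahedral slab mesh
#'
#' A `heart_mesh`-compatible slab of `nx` x `ny` x `nz` elements with uniform
#' spacing `h` (mm), uniform fiber direction, and tagged outer faces. Useful
#' for conduction-velocity measurements, patch tests and oracle checks.
#'
#' @param nx,ny,nz element counts along x, y, z.
#' @param h element edge length (mm); may be length 3 for anisotropic spacing.
#' @param fiber uniform fiber direction (defaults to +x).
#' @return a `heart_mesh` (slab variant; `elem$region = "slab"`).
#' @export
make_slab_mesh <- function(nx, ny = 1, nz = 1, h = 1, fiber = c(1, 0, 0)) {
  stopifnot(nx >= 1, ny >= 1, nz >= 1, all(h > 0))
  h <- rep(h, length.out = 3)
  nid <- function(i, j, k) k * (nx + 1) * (ny + 1) + j * (nx + 1) + i + 1
  g <- expand.grid(i = 0:nx, j = 0:ny, k = 0:nz)
  nodes <- cbind(g$i * h[1], g$j * h[2], g$k * h[3])[order(nid(g$i, g$j, g$k)), , drop = FALSE]
  # order(): expand.grid already emits in nid order, but keep it explicit
  elems <- matrix(0L, nx * ny * nz, 8)
  idx <- 0
  for (k in 0:(nz - 1)) for (j in 0:(ny - 1)) for (i in 0:(nx - 1)) {
    idx <- idx + 1
    elems[idx, ] <- c(nid(i, j, k), nid(i + 1, j, k), nid(i + 1, j + 1, k),
                      nid(i, j + 1, k), nid(i, j, k + 1), nid(i + 1, j, k + 1),
                      nid(i + 1, j + 1, k + 1), nid(i, j + 1, k + 1))
  }
  f <- fiber / sqrt(sum(fiber^2))
  m <- nrow(elems)
  elem <- tibble::tibble(region = "slab", itheta = NA_integer_,
                         ilong = NA_integer_, itrans = NA_integer_,
                         layer = 1L, theta_c = NA_real_, depth = NA_real_,
                         segment = "slab")[rep(1, m), ]
  structure(list(
    nodes = nodes, elems = elems, elem = elem,
    fiber = matrix(f, m, 3, byrow = TRUE),
    surfaces = list(), geom = list(spec = NULL, h = h, n = c(nx, ny, nz)),
    conduction = list(fast_shell = rep(FALSE, m), velocity_scale_fast = 1)),
    class = "heart_mesh")
}

#' Prescribed analytic activation map
#'
#' @param mesh a `heart_mesh`.
#' @param pattern one of `"uniform"` (all nodes at `t0`), `"linear"`
#'   (gradient `slope` ms/mm along `axis` from the mesh minimum), or
#'   `"two_zone"` (septal elements' nodes at `t0`, all others at
#'   `t0 + offset`; heart meshes only).
#' @param t0 base time (ms).
#' @param axis coordinate axis (1-3) for the linear pattern.
#' @param slope ms per mm for the linear pattern.
#' @param offset late-zone offset (ms) for the two-zone pattern.
#' @return an `activation_map`.
#' @export
make_activation_fixture <- function(mesh, pattern = c("uniform", "linear", "two_zone"),
                                    t0 = 0, axis = 1, slope = 1, offset = 60) {
  pattern <- match.arg(pattern)
  n <- nrow(mesh$nodes)
  t_act <- switch(pattern,
    uniform = rep(t0, n),
    linear = t0 + slope * (mesh$nodes[, axis] - min(mesh$nodes[, axis])),
    two_zone = {
      if (!"segment" %in% names(mesh$elem) || all(mesh$elem$segment == "slab"))
        stop("two_zone pattern needs a labelled heart mesh")
      early <- unique(as.vector(mesh$elems[mesh$elem$segment == "septum", ]))
      out <- rep(t0 + offset, n)
      out[early] <- t0
      out
    })
  structure(as.numeric(t_act), class = "activation_map")
}

#' Analytic ring-strain series with prescribed harmonic content
#'
#' Generates a circumferential strain series
#' eps(theta_j) = c + a * sin(theta_j + phase) replicated over `n_slices`
#' short-axis slices and `n_frames` time frames. Its closed-form CURE is
#' sqrt(c^2 / (c^2 + 2 a^2)), which makes this fixture the core contract for
#' the mechanical synchrony index: (c, a) = (1, 0) gives CURE = 1 (perfect
#' synchrony) and (0, 1) gives CURE = 0 (pure first-harmonic dyssynchrony).
#'
#' @param c0 mean (zero-order) strain level.
#' @param a1 first circumferential harmonic amplitude.
#' @param phase phase of the first harmonic (rad).
#' @param n_samples circumferential samples per ring (default 30).
#' @param n_frames number of time frames.
#' @param n_slices number of short-axis slices (default 4, layers 6-9).
#' @return a tibble with columns `slice`, `frame_ms`, `sample`, `theta`,
#'   `ecc`, carrying attribute `ring_spec` with the generating parameters.
#' @export
make_ring_series <- function(c0, a1, phase = 0, n_samples = 30,
                             n_frames = 10, n_slices = 4) {
  stopifnot(n_samples >= 4, n_frames >= 1, n_slices >= 1)
  theta <- 2 * pi * (seq_len(n_samples) - 1) / n_samples
  out <- tidyr::expand_grid(slice = seq_len(n_slices),
                            frame_ms = 10 * (seq_len(n_frames) - 1),
                            sample = seq_len(n_samples))
  out$theta <- theta[out$sample]
  out$ecc <- c0 + a1 * sin(out$theta + phase)
  attr(out, "ring_spec") <- list(c0 = c0, a1 = a1, phase = phase,
                                 n_samples = n_samples, n_frames = n_frames,
                                 n_slices = n_slices)
  out
}

#' Closed triangulated sphere surface fixture
#'
#' Latitude/longitude triangulation of a sphere of radius `r` (mm), used to
#' validate the divergence-theorem cavity volume against 4/3 pi r^3.
#'
#' @param r radius (mm).
#' @param n_theta,n_phi longitudinal/latitudinal resolution.
#' @return list with `vertices` (V x 3) and `triangles` (T x 3 indices),
#'   outward orientation.
#' @export
make_sphere_surface <- function(r = 10, n_theta = 48, n_phi = 24) {
  phi <- seq(0, pi, length.out = n_phi + 1)
  theta <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  # interior ring vertices plus two poles
  verts <- list(c(0, 0, r))
  ring_id <- matrix(0L, n_phi - 1, n_theta)
  id <- 1
  for (j in seq_len(n_phi - 1)) {
    for (i in seq_len(n_theta)) {
      id <- id + 1
      verts[[id]] <- c(r * sin(phi[j + 1]) * cos(theta[i]),
                       r * sin(phi[j + 1]) * sin(theta[i]),
                       r * cos(phi[j + 1]))
      ring_id[j, i] <- id
    }
  }
  south <- id + 1
  verts[[south]] <- c(0, 0, -r)
  tris <- list()
  for (i in seq_len(n_theta)) {
    ip <- i %% n_theta + 1
    tris[[length(tris) + 1]] <- c(1, ring_id[1, i], ring_id[1, ip])
  }
  if (n_phi > 2) for (j in seq_len(n_phi - 2)) for (i in seq_len(n_theta)) {
    ip <- i %% n_theta + 1
    a <- ring_id[j, i]; b <- ring_id[j, ip]
    cpt <- ring_id[j + 1, i]; d <- ring_id[j + 1, ip]
    tris[[length(tris) + 1]] <- c(a, cpt, d)
    tris[[length(tris) + 1]] <- c(a, d, b)
  }
  for (i in seq_len(n_theta)) {
    ip <- i %% n_theta + 1
    tris[[length(tris) + 1]] <- c(south, ring_id[n_phi - 1, ip], ring_id[n_phi - 1, i])
  }
  list(vertices = do.call(rbind, verts), triangles = do.call(rbind, tris))
}
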