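# Idealized two-ellipsoid biventricular hexahedral mesh.
#
# Geometry conventions:
#   * LV long axis = z, apex pointing to negative z, base at the top.
#   * The LV cavity is a truncated ellipsoid (semi-axes `lv_endo_radii`),
#     truncated at the base plane z = base_truncation_fraction * c and at a
#     small polar cap near the apex (a closed apex would need collapsed,
#     zero-Jacobian hexahedra).
#   * Short-axis angle theta: lateral wall at theta = 0 (+x), anterior at
#     +pi/2 (+y), septum at pi (-x), posterior at -pi/2.
#   * The RV free wall is a thin shell bulging radially outward from the LV
#     epicardium over the septal sector; its rim nodes are shared with the
#     LV epicardium so the crescent-shaped RV cavity is closed (when capped
#     at the base plane).

#' Specification of the idealized biventricular mesh
#'
#' @param lv_endo_radii length-3 semi-axes (mm) of the LV cavity ellipsoid
#'   (x, y, z = long axis).
#' @param wall_thickness_lv,wall_thickness_rv,wall_thickness_septum wall
#'   thicknesses in mm.
#' @param n_layers number of longitudinal layers from apex (layer 1) to base
#'   (default 14). Must be >= 9 so the equatorial layers 6-9 exist.
#' @param n_circumferential elements per circumferential ring.
#' @param n_transmural transmural element count across the LV wall.
#' @param base_truncation_fraction base plane height as a fraction of the
#'   long semi-axis, in (0, 1).
#' @param apex_truncation_fraction small fraction of the long semi-axis cut
#'   off at the apex pole to avoid degenerate polar elements.
#' @param rv_sector_deg circumferential extent (degrees) of the RV free wall
#'   attachment, centred on the septum.
#' @param rv_extent fraction of the apex-to-base span covered by the RV
#'   (RV apex sits this fraction below the base).
#' @param rv_gap_mm maximal RV cavity width (mm) between septal epicardium
#'   and RV free wall endocardium.
#' @param n_transmural_rv transmural element count across the RV free wall.
#' @return an object of class `mesh_spec` (a validated list).
#' @export
mesh_spec <- function(lv_endo_radii = c(18, 18, 45),
                      wall_thickness_lv = 8,
                      wall_thickness_rv = 4,
                      wall_thickness_septum = 8,
                      n_layers = 14,
                      n_circumferential = 32,
                      n_transmural = 4,
                      base_truncation_fraction = 0.4,
                      apex_truncation_fraction = 0.01,
                      rv_sector_deg = 120,
                      rv_extent = 0.7,
                      rv_gap_mm = 10,
                      n_transmural_rv = 2) {
  spec <- list(
    lv_endo_radii = as.numeric(lv_endo_radii),
    wall_thickness_lv = wall_thickness_lv,
    wall_thickness_rv = wall_thickness_rv,
    wall_thickness_septum = wall_thickness_septum,
    n_layers = as.integer(n_layers),
    n_circumferential = as.integer(n_circumferential),
    n_transmural = as.integer(n_transmural),
    base_truncation_fraction = base_truncation_fraction,
    apex_truncation_fraction = apex_truncation_fraction,
    rv_sector_deg = rv_sector_deg,
    rv_extent = rv_extent,
    rv_gap_mm = rv_gap_mm,
    n_transmural_rv = as.integer(n_transmural_rv))
  validate_mesh_spec(spec)
  structure(spec, class = "mesh_spec")
}

validate_mesh_spec <- function(spec) {
  if (length(spec$lv_endo_radii) != 3 || any(spec$lv_endo_radii <= 0))
    stop("lv_endo_radii must be 3 positive semi-axes (mm)")
  for (f in c("wall_thickness_lv", "wall_thickness_rv", "wall_thickness_septum"))
    if (spec[[f]] <= 0) stop(f, " must be > 0")
  if (spec$n_layers < 9)
    stop("n_layers must be >= 9 so equatorial layers 6-9 exist")
  if (spec$n_circumferential < 8) stop("n_circumferential must be >= 8")
  if (spec$n_transmural < 1 || spec$n_transmural_rv < 1)
    stop("transmural element counts must be >= 1")
  if (spec$base_truncation_fraction <= 0 || spec$base_truncation_fraction >= 1)
    stop("base_truncation_fraction must be in (0, 1)")
  if (spec$apex_truncation_fraction <= 0 || spec$apex_truncation_fraction >= 0.2)
    stop("apex_truncation_fraction must be in (0, 0.2)")
  invisible(spec)
}

# local wall thickness: smooth blend from free-wall to septal thickness
.wall_thickness <- function(theta, spec) {
  half <- spec$rv_sector_deg * pi / 360
  d <- abs(atan2(sin(theta - pi), cos(theta - pi)))   # angle from septal bisector
  w <- ifelse(d < half, cos(pi * d / half / 2)^2, 0)
  spec$wall_thickness_lv + (spec$wall_thickness_septum - spec$wall_thickness_lv) * w
}

.endo_pt <- function(theta, phi, spec) {
  r <- spec$lv_endo_radii
  cbind(r[1] * sin(phi) * cos(theta), r[2] * sin(phi) * sin(theta), -r[3] * cos(phi))
}

.epi_pt <- function(theta, phi, spec) {
  r <- spec$lv_endo_radii
  th <- .wall_thickness(theta, spec)
  cbind((r[1] + th) * sin(phi) * cos(theta),
        (r[2] + th) * sin(phi) * sin(theta),
        -(r[3] + spec$wall_thickness_lv) * cos(phi))
}

.wall_pt <- function(theta, phi, t, spec) {
  (1 - t) * .endo_pt(theta, phi, spec) + t * .epi_pt(theta, phi, spec)
}

# longitudinal phi levels: equal-height bands in endocardial z
.phi_levels <- function(spec) {
  cc <- spec$lv_endo_radii[3]
  z_apex <- -cc * (1 - spec$apex_truncation_fraction)
  z_base <- cc * spec$base_truncation_fraction
  z <- seq(z_apex, z_base, length.out = spec$n_layers + 1)
  acos(pmin(1, pmax(-1, -z / cc)))
}

#' Analytic LV cavity volume of the truncated-ellipsoid idealization
#'
#' Volume (mL) of the endocardial ellipsoid between the apical truncation
#' plane and the base plane; the converged limit of [cavity_volume()] on the
#' undeformed mesh.
#'
#' @param spec a [mesh_spec()].
#' @return volume in mL.
#' @export
analytic_cavity_volume <- function(spec) {
  r <- spec$lv_endo_radii
  cc <- r[3]
  z0 <- -cc * (1 - spec$apex_truncation_fraction)
  z1 <- cc * spec$base_truncation_fraction
  f <- function(z) z - z^3 / (3 * cc^2)
  pi * r[1] * r[2] * (f(z1) - f(z0)) / 1000
}

#' Build the idealized biventricular hexahedral mesh
#'
#' Constructs a watertight two-cavity truncated-ellipsoid mesh: a thick-walled
#' LV shell plus a thin RV free wall attached over the septal sector, with
#' layer indices assigned by equal longitudinal bands from apex (layer 1) to
#' base (layer `n_layers`). Fibers (default +60/-60 degree transmural helix),
#' wall-segment labels and the conduction-system configuration are assigned.
#' Every element's Jacobian determinant is verified positive.
#'
#' @param spec a [mesh_spec()].
#' @param endo_angle,epi_angle fiber helix angles (degrees) at endo-/epicardium.
#' @return an object of class `heart_mesh`: a list with `nodes` (N x 3, mm),
#'   `elems` (M x 8 connectivity), `elem` (per-element tibble with `region`,
#'   `layer`, `segment`, ...), `fiber` (M x 3 unit vectors), `surfaces`
#'   (face-node matrices `lv_endo`, `rv_endo`, `epi`, `base`), and
#'   `conduction` (fast-shell mask and bundle entry nodes).
#' @export
build_biventricular_mesh <- function(spec = mesh_spec(),
                                     endo_angle = 60, epi_angle = -60) {
  if (!inherits(spec, "mesh_spec")) spec <- do.call(mesh_spec, spec)
  nc <- spec$n_circumferential
  nl <- spec$n_layers
  nt <- spec$n_transmural
  theta <- 2 * pi * (seq_len(nc) - 1) / nc
  phi <- .phi_levels(spec)

  # ---- LV nodes: index (i_theta, j_long, k_trans) -------------------------
  lv_id <- function(i, j, k) k * (nl + 1) * nc + j * nc + (i %% nc) + 1
  n_lv <- (nt + 1) * (nl + 1) * nc
  nodes <- matrix(0, n_lv, 3)
  for (k in 0:nt) for (j in 0:nl) {
    t <- k / nt
    nodes[lv_id(0:(nc - 1), j, k), ] <- .wall_pt(theta, phi[j + 1], t, spec)
  }

  # ---- LV elements --------------------------------------------------------
  lv_elems <- vector("list", nc * nl * nt)
  lv_meta <- vector("list", nc * nl * nt)
  idx <- 0
  for (k in 0:(nt - 1)) for (j in 0:(nl - 1)) for (i in 0:(nc - 1)) {
    idx <- idx + 1
    lv_elems[[idx]] <- c(lv_id(i, j, k),     lv_id(i + 1, j, k),
                         lv_id(i + 1, j + 1, k), lv_id(i, j + 1, k),
                         lv_id(i, j, k + 1), lv_id(i + 1, j, k + 1),
                         lv_id(i + 1, j + 1, k + 1), lv_id(i, j + 1, k + 1))
    lv_meta[[idx]] <- c(i, j, k)
  }

  # ---- RV free wall -------------------------------------------------------
  half_w <- spec$rv_sector_deg * pi / 360
  dth <- 2 * pi / nc
  i_start <- round((pi - half_w) / dth)
  i_end <- round((pi + half_w) / dth)
  j_rv <- max(1L, round(nl * (1 - spec$rv_extent)))
  ntr <- spec$n_transmural_rv

  gap_fun <- function(i, j) {
    if (i <= i_start || i >= i_end || j <= j_rv) return(0)
    bt <- sin(pi * (i - i_start) / (i_end - i_start))
    s <- (j - j_rv) / (nl - j_rv)
    bj <- sin(min(1, s / 0.6) * pi / 2)
    spec$rv_gap_mm * bt * bj
  }

  rv_cols <- expand.grid(i = i_start:i_end, j = j_rv:nl)
  rv_inner_id <- matrix(NA_integer_, nrow = i_end - i_start + 1, ncol = nl - j_rv + 1)
  rv_outer_id <- array(NA_integer_, dim = c(i_end - i_start + 1, nl - j_rv + 1, ntr))
  extra_nodes <- list()
  next_id <- n_lv
  for (r in seq_len(nrow(rv_cols))) {
    i <- rv_cols$i[r]; j <- rv_cols$j[r]
    ii <- i - i_start + 1; jj <- j - j_rv + 1
    g <- gap_fun(i, j)
    rhat <- c(cos(theta[(i %% nc) + 1]), sin(theta[(i %% nc) + 1]), 0)
    p_epi <- drop(.epi_pt(theta[(i %% nc) + 1], phi[j + 1], spec))
    if (g == 0) {
      rv_inner_id[ii, jj] <- lv_id(i, j, nt)
    } else {
      next_id <- next_id + 1
      extra_nodes[[length(extra_nodes) + 1]] <- p_epi + g * rhat
      rv_inner_id[ii, jj] <- next_id
    }
    for (k2 in seq_len(ntr)) {
      next_id <- next_id + 1
      extra_nodes[[length(extra_nodes) + 1]] <-
        p_epi + (g + spec$wall_thickness_rv * k2 / ntr) * rhat
      rv_outer_id[ii, jj, k2] <- next_id
    }
  }
  nodes <- rbind(nodes, do.call(rbind, extra_nodes))

  rv_node_at <- function(i, j, k2) {
    ii <- i - i_start + 1; jj <- j - j_rv + 1
    if (k2 == 0) rv_inner_id[ii, jj] else rv_outer_id[ii, jj, k2]
  }
  rv_elems <- list(); rv_meta <- list()
  for (k2 in 0:(ntr - 1)) for (j in j_rv:(nl - 1)) for (i in i_start:(i_end - 1)) {
    rv_elems[[length(rv_elems) + 1]] <-
      c(rv_node_at(i, j, k2), rv_node_at(i + 1, j, k2),
        rv_node_at(i + 1, j + 1, k2), rv_node_at(i, j + 1, k2),
        rv_node_at(i, j, k2 + 1), rv_node_at(i + 1, j, k2 + 1),
        rv_node_at(i + 1, j + 1, k2 + 1), rv_node_at(i, j + 1, k2 + 1))
    rv_meta[[length(rv_meta) + 1]] <- c(i, j, k2)
  }

  elems <- rbind(do.call(rbind, lv_elems), do.call(rbind, rv_elems))
  storage.mode(elems) <- "integer"
  m_lv <- length(lv_elems); m_rv <- length(rv_elems)
  meta <- rbind(do.call(rbind, lv_meta), do.call(rbind, rv_meta))

  elem <- tibble::tibble(
    region = rep(c("lv", "rv"), c(m_lv, m_rv)),
    itheta = meta[, 1] %% nc,
    ilong = meta[, 2],
    itrans = meta[, 3],
    layer = as.integer(meta[, 2] + 1),
    theta_c = (meta[, 1] + 0.5) * dth,
    depth = ifelse(rep(c(TRUE, FALSE), c(m_lv, m_rv)),
                   (meta[, 3] + 0.5) / nt, (meta[, 3] + 0.5) / ntr))
  elem$theta_c <- atan2(sin(elem$theta_c), cos(elem$theta_c))

  # ---- surfaces -----------------------------------------------------------
  face_of <- function(conn, which) {
    # local faces of the VTK hexahedron by local node index
    f <- switch(which,
      bottom = c(1, 4, 3, 2), top = c(5, 6, 7, 8),
      south = c(1, 2, 6, 5), north = c(4, 8, 7, 3),
      west = c(1, 5, 8, 4), east = c(2, 3, 7, 6))
    conn[f]
  }
  lv_endo_faces <- list(); epi_faces <- list(); base_faces <- list()
  rv_endo_faces <- list()
  for (e in seq_len(m_lv)) {
    i <- meta[e, 1]; j <- meta[e, 2]; k <- meta[e, 3]
    conn <- elems[e, ]
    if (k == 0) lv_endo_faces[[length(lv_endo_faces) + 1]] <- face_of(conn, "bottom")
    if (k == nt - 1) {
      covered <- i >= i_start && i < i_end && j >= j_rv &&
        (gap_fun(i, j + 1) > 0 || gap_fun(i + 1, j + 1) > 0)
      if (covered) rv_endo_faces[[length(rv_endo_faces) + 1]] <- face_of(conn, "top")
      else epi_faces[[length(epi_faces) + 1]] <- face_of(conn, "top")
    }
    if (j == nl - 1) base_faces[[length(base_faces) + 1]] <- face_of(conn, "north")
  }
  for (e in seq_len(m_rv)) {
    conn <- elems[m_lv + e, ]
    i <- meta[m_lv + e, 1]; j <- meta[m_lv + e, 2]; k2 <- meta[m_lv + e, 3]
    if (k2 == 0) rv_endo_faces[[length(rv_endo_faces) + 1]] <- face_of(conn, "bottom")
    if (k2 == ntr - 1) epi_faces[[length(epi_faces) + 1]] <- face_of(conn, "top")
    if (j == nl - 1) base_faces[[length(base_faces) + 1]] <- face_of(conn, "north")
  }
  surfaces <- list(
    lv_endo = do.call(rbind, lv_endo_faces),
    rv_endo = do.call(rbind, rv_endo_faces),
    epi = do.call(rbind, epi_faces),
    base = do.call(rbind, base_faces))

  geom <- list(spec = spec, theta = theta, phi = phi, n_lv_elems = m_lv,
               i_start = i_start, i_end = i_end, j_rv = j_rv,
               lv_endo_ring_apex = lv_id(0:(nc - 1), 0, 0),
               lv_endo_ring_base = lv_id(0:(nc - 1), nl, 0))

  mesh <- structure(list(
    nodes = nodes, elems = elems, elem = elem, surfaces = surfaces,
    geom = geom, fiber = NULL, conduction = NULL), class = "heart_mesh")

  # Jacobian validity
  dj <- mesh_min_detJ(mesh)
  bad <- which(!is.finite(dj) | dj <= 0)
  if (length(bad) > 0)
    stop("degenerate mesh spec: non-positive Jacobian in element(s) ",
         paste(utils::head(bad, 5), collapse = ", "))

  mesh <- label_segments(mesh)
  mesh <- assign_fiber_orientations(mesh, endo_angle, epi_angle)
  mesh$conduction <- default_conduction_config(mesh)
  mesh
}

# structured LV node id from (i_theta, j_long, k_trans)
lv_node_id <- function(geom, i, j, k) {
  nc <- geom$spec$n_circumferential
  nl <- geom$spec$n_layers
  k * (nl + 1) * nc + j * nc + (i %% nc) + 1
}

#' Minimum Jacobian determinant per element
#' @param mesh a `heart_mesh`.
#' @return numeric vector, one minimum-over-quadrature detJ per element.
#' @export
mesh_min_detJ <- function(mesh) {
  quad <- hex_quadrature(2)
  vapply(seq_len(nrow(mesh$elems)), function(e) {
    hex_min_detJ(mesh$nodes[mesh$elems[e, ], , drop = FALSE], quad)
  }, numeric(1))
}

#' Label LV wall segments by circumferential quadrant
#'
#' Every LV element receives exactly one of `septum`, `anterior`, `lateral`,
#' `posterior` by the quadrant of its centre angle about the LV long axis
#' (septum centred on the RV attachment bisector, lateral diametrically
#' opposite, anterior/posterior in between); RV free-wall elements are
#' labelled `rv_free_wall`. Idempotent.
#'
#' @param mesh a `heart_mesh`.
#' @return the mesh with `mesh$elem$segment` filled in.
#' @export
label_segments <- function(mesh) {
  th <- mesh$elem$theta_c
  d_sept <- abs(atan2(sin(th - pi), cos(th - pi)))
  d_lat <- abs(atan2(sin(th), cos(th)))
  d_ant <- abs(atan2(sin(th - pi / 2), cos(th - pi / 2)))
  seg <- ifelse(d_sept <= pi / 4, "septum",
         ifelse(d_lat <= pi / 4, "lateral",
         ifelse(d_ant <= pi / 4, "anterior", "posterior")))
  seg[mesh$elem$region == "rv"] <- "rv_free_wall"
  mesh$elem$segment <- seg
  mesh
}

#' Assign a rule-based transmural helix fiber field
#'
#' Each element's fiber unit vector lies in its local circumferential-
#' longitudinal plane, with the helix angle interpolated linearly in
#' normalized transmural depth from `endo_angle` (endocardium) to
#' `epi_angle` (epicardium). Deterministic given (mesh, angles).
#'
#' @param mesh a `heart_mesh`.
#' @param endo_angle,epi_angle helix angles in degrees, in \[-90, 90\].
#' @return the mesh with `mesh$fiber` set (M x 3 unit vectors).
#' @export
assign_fiber_orientations <- function(mesh, endo_angle = 60, epi_angle = -60) {
  stopifnot(abs(endo_angle) <= 90, abs(epi_angle) <= 90)
  m <- nrow(mesh$elems)
  fib <- matrix(0, m, 3)
  for (e in seq_len(m)) {
    X <- mesh$nodes[mesh$elems[e, ], , drop = FALSE]
    ctr <- colMeans(X)
    th <- atan2(ctr[2], ctr[1])
    e_c <- c(-sin(th), cos(th), 0)
    # longitudinal direction: edge midpoint top minus bottom (local eta axis)
    e_l <- colMeans(X[c(3, 4, 7, 8), ]) - colMeans(X[c(1, 2, 5, 6), ])
    e_l <- e_l - sum(e_l * e_c) * e_c
    nl <- sqrt(sum(e_l^2))
    if (nl < 1e-9) e_l <- c(0, 0, 1) else e_l <- e_l / nl
    d <- mesh$elem$depth[e]
    alpha <- (endo_angle + (epi_angle - endo_angle) * d) * pi / 180
    f <- cos(alpha) * e_c + sin(alpha) * e_l
    fib[e, ] <- f / sqrt(sum(f^2))
  }
  mesh$fiber <- fib
  mesh
}

#' Default conduction-system configuration
#'
#' Marks the endocardial fast-conduction shell (one element thick on both
#' ventricular endocardia, standing in for the Purkinje network) and resolves
#' the left/right bundle entry nodes at the septal base. The left bundle
#' enters on the LV septal endocardium, the right bundle on the RV-facing
#' septal surface.
#'
#' @param mesh a `heart_mesh`.
#' @param velocity_scale_fast diffusion multiplier inside the fast shell.
#' @param lbbb logical; if `TRUE` the left bundle receives no stimulus under
#'   the pathological protocol.
#' @return a list with `fast_shell` (logical per element), `left_bundle_site`,
#'   `right_bundle_site` (node ids), `lbbb`, `velocity_scale_fast`.
#' @export
default_conduction_config <- function(mesh, velocity_scale_fast = 6, lbbb = TRUE) {
  el <- mesh$elem
  g <- mesh$geom
  nt <- g$spec$n_transmural
  fast <- (el$region == "lv" & el$itrans == 0) |
    (el$region == "rv" & el$itrans == 0) |
    (el$region == "lv" & el$itrans == nt - 1 & el$segment == "septum" &
       el$ilong >= g$j_rv)
  nl <- g$spec$n_layers
  nc <- g$spec$n_circumferential
  i_sept <- round(pi / (2 * pi / nc)) %% nc
  left_site <- lv_node_id(g, i_sept, nl - 1, 0)
  right_site <- lv_node_id(g, i_sept, nl - 1, nt)
  list(fast_shell = fast, left_bundle_site = left_site,
       right_bundle_site = right_site, lbbb = lbbb,
       velocity_scale_fast = velocity_scale_fast)
}

#' Catalogue of the seven default pacing lead sites
#'
#' Returns the right-ventricular apex lead (RVA, the RV endocardial node
#' nearest the apex) plus the six LV epicardial sites
#' \{POST, LAT, ANT\} x \{B = base, E = equator\}. Equator sites resolve to
#' epicardial nodes adjacent to layers 6-9; base sites to the top two layers
#' below the base ring.
#'
#' @param mesh a labelled `heart_mesh`.
#' @return a tibble with columns `name`, `wall`, `circumferential_position`,
#'   `longitudinal_level`, `node_id`.
#' @export
default_lead_sites <- function(mesh) {
  g <- mesh$geom
  spec <- g$spec
  nl <- spec$n_layers

  # RVA: RV endocardial node nearest the apex
  rv_endo_nodes <- unique(as.vector(mesh$surfaces$rv_endo))
  apex <- c(0, 0, -(spec$lv_endo_radii[3] + spec$wall_thickness_lv))
  d <- sqrt(rowSums((mesh$nodes[rv_endo_nodes, , drop = FALSE] -
                       matrix(apex, length(rv_endo_nodes), 3, byrow = TRUE))^2))
  rva_node <- rv_endo_nodes[which.min(d)]

  epi_nodes <- unique(as.vector(mesh$surfaces$epi))
  seg_center <- c(posterior = -pi / 2, lateral = 0, anterior = pi / 2)
  level_layers <- list(B = c(nl - 1L, nl), E = 6:9)

  resolve_lv <- function(seg, level) {
    layers <- level_layers[[level]]
    el_ok <- which(mesh$elem$region == "lv" & mesh$elem$segment == seg &
                     mesh$elem$layer %in% layers)
    if (length(el_ok) == 0)
      stop("unresolvable lead site: no epicardial element with segment ", seg,
           " in layers ", paste(range(layers), collapse = "-"))
    cand <- intersect(unique(as.vector(mesh$elems[el_ok, ])), epi_nodes)
    if (length(cand) == 0)
      stop("unresolvable lead site: segment ", seg, " has no epicardial node")
    # target point: segment centre angle at mid of the layer band, on epi
    phi_mid <- mean(g$phi[c(min(layers), max(layers) + 1)])
    target <- drop(.epi_pt(seg_center[[seg]], phi_mid, spec))
    dd <- sqrt(rowSums((mesh$nodes[cand, , drop = FALSE] -
                          matrix(target, length(cand), 3, byrow = TRUE))^2))
    cand[which.min(dd)]
  }

  sites <- tibble::tibble(
    name = c("RVA", "POST-B", "POST-E", "LAT-B", "LAT-E", "ANT-B", "ANT-E"),
    wall = c("rv_endo_apex", rep("lv_epi", 6)),
    circumferential_position = c(NA, "posterior", "posterior", "lateral",
                                 "lateral", "anterior", "anterior"),
    longitudinal_level = c("apex", "base", "equator", "base", "equator",
                           "base", "equator"))
  sites$node_id <- c(rva_node,
                     resolve_lv("posterior", "B"), resolve_lv("posterior", "E"),
                     resolve_lv("lateral", "B"), resolve_lv("lateral", "E"),
                     resolve_lv("anterior", "B"), resolve_lv("anterior", "E"))
  sites
}

#' @export
print.heart_mesh <- function(x, ...) {
  cat("<heart_mesh>\n")
  cat("  nodes:    ", nrow(x$nodes), "\n")
  cat("  hexahedra:", nrow(x$elems),
      sprintf(" (lv %d, rv %d)\n", sum(x$elem$region == "lv"),
              sum(x$elem$region == "rv")))
  if (!is.null(x$geom$spec))
    cat("  layers:   ", x$geom$spec$n_layers, " (apex = 1)\n")
  invisible(x)
}
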