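# Monodomain excitation propagation.
#
# The transmembrane potential is normalized (rest = 0, peak ~ 1). Local
# kinetics are the two-variable Aliev-Panfilov excitable model (cubic
# upstroke, recovery variable giving an absolute refractory period), scaled
# to physical milliseconds by `tau_ms`. Spatial coupling uses trilinear
# finite elements with a lumped mass matrix; time stepping is operator
# splitting: explicit reaction substep, then implicit (backward Euler)
# diffusion substep with a pre-factored sparse Cholesky solve.

#' Monodomain and kinetics parameters
#'
#' @param d_long,d_trans diffusion coefficients along/across fiber
#'   (mm^2/ms) before the common monodomain scaling.
#' @param beta surface-to-volume ratio (1/mm); the diffusion tensor carries
#'   the monodomain scaling (1/beta) * k/(k+1).
#' @param k_ratio intra-/extracellular anisotropy ratio (dimensionless).
#' @param c_m membrane capacitance (uF/cm^2); scales applied current.
#' @param dt time step (ms).
#' @param t_end simulation horizon (ms).
#' @param threshold activation threshold on the normalized upstroke.
#' @param frame_every snapshot interval in steps for stored frames.
#' @param tau_ms time scale (ms per kinetics time unit).
#' @param ap_k,ap_a,ap_eps0,ap_mu1,ap_mu2 Aliev-Panfilov constants.
#' @return object of class `monodomain_params`.
#' @export
monodomain_params <- function(d_long = 5.0, d_trans = 1.25,
                              beta = 1, k_ratio = 1,
                              c_m = 1, dt = 0.1, t_end = 250,
                              threshold = 0.5, frame_every = 5,
                              tau_ms = 12.9,
                              ap_k = 8, ap_a = 0.15, ap_eps0 = 0.002,
                              ap_mu1 = 0.2, ap_mu2 = 0.3) {
  stopifnot(d_long >= d_trans, d_trans > 0, dt > 0, t_end >= dt,
            threshold > 0, threshold < 1, beta > 0, k_ratio > 0)
  structure(list(d_long = d_long, d_trans = d_trans, beta = beta,
                 k_ratio = k_ratio, c_m = c_m, dt = dt, t_end = t_end,
                 threshold = threshold, frame_every = as.integer(frame_every),
                 tau_ms = tau_ms, ap_k = ap_k, ap_a = ap_a,
                 ap_eps0 = ap_eps0, ap_mu1 = ap_mu1, ap_mu2 = ap_mu2),
            class = "monodomain_params")
}

#' A pacing/bundle stimulus
#'
#' @param nodes node ids receiving the stimulus.
#' @param onset onset time (ms).
#' @param amplitude stimulus current density (uA/cm^2), default 100.
#' @param duration stimulus duration (ms), default 0.5.
#' @return object of class `stimulus`.
#' @export
stimulus <- function(nodes, onset = 0, amplitude = 100, duration = 0.5) {
  stopifnot(length(nodes) >= 1, duration > 0, amplitude > 0, onset >= 0)
  structure(list(nodes = as.integer(nodes), onset = onset,
                 amplitude = amplitude, duration = duration),
            class = "stimulus")
}

#' Advance the local ionic kinetics by one step (no spatial coupling)
#'
#' Explicit Euler update of the Aliev-Panfilov reaction system
#' du/dt = (k u (u - a)(1 - u) - u v + I) / tau,
#' dv/dt = eps(u, v) (-v - k u (u - a - 1)) / tau.
#' A resting node with no applied current is a fixed point.
#'
#' @param state list with numeric vectors `v` (normalized potential) and
#'   `w` (recovery variable).
#' @param dt time step (ms).
#' @param params [monodomain_params()].
#' @param i_app applied current (normalized, same length as `state$v` or
#'   scalar), default 0.
#' @return updated state list.
#' @export
reaction_step <- function(state, dt, params, i_app = 0) {
  u <- state$v; w <- state$w
  if (any(!is.finite(u)) || any(!is.finite(w)))
    stop("non-finite ionic state at node(s) ",
         paste(utils::head(which(!is.finite(u) | !is.finite(w)), 5), collapse = ", "))
  p <- params
  du <- p$ap_k * u * (u - p$ap_a) * (1 - u) - u * w + i_app
  eps <- p$ap_eps0 + p$ap_mu1 * w / (u + p$ap_mu2)
  dw <- eps * (-w - p$ap_k * u * (u - p$ap_a - 1))
  list(v = u + dt * du / p$tau_ms, w = w + dt * dw / p$tau_ms)
}

#' Anisotropic monodomain diffusion tensor for one element
#'
#' D = D_trans I + (D_long - D_trans) f f^T, scaled by (1/beta) * k/(k+1);
#' elements in the fast-conduction shell are additionally multiplied by
#' `fast_scale`.
#'
#' @param fiber unit fiber vector.
#' @param params [monodomain_params()].
#' @param fast_scale diffusion multiplier (1 outside the fast shell).
#' @return 3 x 3 symmetric positive definite tensor (mm^2/ms).
#' @export
diffusion_tensor <- function(fiber, params, fast_scale = 1) {
  f <- fiber / sqrt(sum(fiber^2))
  D <- params$d_trans * diag(3) +
    (params$d_long - params$d_trans) * tcrossprod(f)
  scale <- (1 / params$beta) * params$k_ratio / (params$k_ratio + 1)
  scale * fast_scale * D
}

# assemble global lumped mass vector and diffusion stiffness matrix
assemble_monodomain <- function(mesh, params) {
  m <- nrow(mesh$elems)
  n <- nrow(mesh$nodes)
  fast <- mesh$conduction$fast_shell
  if (is.null(fast)) fast <- rep(FALSE, m)
  vfast <- mesh$conduction$velocity_scale_fast %||% 1
  quad <- hex_quadrature(2)
  ii <- vector("list", m); jj <- vector("list", m); xx <- vector("list", m)
  mass <- numeric(n)
  for (e in seq_len(m)) {
    conn <- mesh$elems[e, ]
    X <- mesh$nodes[conn, , drop = FALSE]
    D <- diffusion_tensor(mesh$fiber[e, ], params,
                          if (fast[e]) vfast else 1)
    Ke <- hex_diffusion_stiffness(X, D, quad)
    mass[conn] <- mass[conn] + hex_lumped_mass(X, quad)
    ii[[e]] <- rep(conn, times = 8)
    jj[[e]] <- rep(conn, each = 8)
    xx[[e]] <- as.vector(Ke)
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n, n))
  list(K = Matrix::forceSymmetric(K), mass = mass)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a monodomain simulation
#'
#' Operator-split stepping: an explicit reaction substep followed by an
#' implicit backward-Euler diffusion substep on the finite-element
#' discretization with lumped mass (natural no-flux boundary). Snapshots of
#' the normalized potential are stored every `params$frame_every` steps.
#'
#' @param mesh a `heart_mesh` with fibers (and optionally a conduction
#'   configuration providing the fast shell).
#' @param params [monodomain_params()].
#' @param stimuli list of [stimulus()] objects.
#' @return object of class `vm_series`: list with `times` (ms) and `frames`
#'   (n_nodes x n_frames matrix of normalized potential).
#' @export
run_monodomain <- function(mesh, params, stimuli = list()) {
  if (inherits(stimuli, "stimulus")) stimuli <- list(stimuli)
  sys <- assemble_monodomain(mesh, params)
  n <- nrow(mesh$nodes)
  dt <- params$dt
  n_steps <- ceiling(params$t_end / dt)
  # (M + dt K) v_new = M v*  with lumped M
  A <- Matrix::Diagonal(x = sys$mass) + dt * sys$K
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
  u <- numeric(n); w <- numeric(n)
  keep <- seq(0, n_steps, by = params$frame_every)
  frames <- matrix(0, n, length(keep))
  times <- keep * dt
  fi <- 1
  frames[, 1] <- u
  # the protocol amplitude (100 uA/cm^2) maps to a suprathreshold
  # normalized drive through c_m
  for (s in seq_len(n_steps)) {
    t0 <- (s - 1) * dt
    i_app <- numeric(n)
    for (st in stimuli) {
      if (t0 >= st$onset && t0 < st$onset + st$duration)
        i_app[st$nodes] <- i_app[st$nodes] +
          st$amplitude / (100 * params$c_m) * 2 * params$tau_ms / st$duration
    }
    stt <- reaction_step(list(v = u, w = w), dt, params, i_app)
    w <- stt$w
    u <- as.numeric(Matrix::solve(ch, sys$mass * stt$v))
    if (any(!is.finite(u)))
      stop("monodomain solver produced non-finite values at step ", s)
    if (s %in% keep) {
      fi <- fi + 1
      frames[, fi] <- u
    }
  }
  structure(list(times = times, frames = frames, threshold = params$threshold),
            class = "vm_series")
}

#' Extract nodal activation times from a potential time series
#'
#' The activation time is the first linearly interpolated upstroke crossing
#' of `threshold`; nodes that never cross get `NA` (unactivated sentinel).
#'
#' @param series a `vm_series` from [run_monodomain()].
#' @param threshold crossing level; defaults to the one stored in `series`.
#' @return an `activation_map`: numeric vector of per-node times (ms) with
#'   attribute `n_nodes`.
#' @export
extract_activation_times <- function(series, threshold = NULL) {
  thr <- threshold %||% series$threshold
  fr <- series$frames
  tt <- series$times
  n <- nrow(fr)
  t_act <- rep(NA_real_, n)
  above <- fr >= thr
  for (i in seq_len(n)) {
    idx <- which(above[i, ])
    if (length(idx) == 0) next
    k <- idx[1]
    if (k == 1) { t_act[i] <- tt[1]; next }
    v0 <- fr[i, k - 1]; v1 <- fr[i, k]
    t_act[i] <- tt[k - 1] + (thr - v0) / (v1 - v0) * (tt[k] - tt[k - 1])
  }
  structure(t_act, class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  act <- unclass(x)
  cat("<activation_map> ", length(act), " nodes; ",
      sum(is.na(act)), " unactivated\n", sep = "")
  if (any(!is.na(act)))
    cat(sprintf("  range %.1f - %.1f ms\n", min(act, na.rm = TRUE),
                max(act, na.rm = TRUE)))
  invisible(x)
}

#' Tidy an activation map into a tibble
#' @param x an `activation_map`.
#' @param ... unused.
#' @return tibble with `node_id`, `t_act_ms`.
#' @exportS3Method generics::tidy
tidy.activation_map <- function(x, ...) {
  tibble::tibble(node_id = seq_along(unclass(x)), t_act_ms = as.numeric(x))
}

#' Nodes within the capture footprint of an electrode
#'
#' A point stimulus cannot ignite a propagating wave whose natural front
#' width exceeds the mesh spacing; physical electrodes capture a small
#' tissue region. Returns all mesh nodes within `radius` mm of `node`.
#'
#' @param mesh a `heart_mesh`.
#' @param node centre node id.
#' @param radius capture radius (mm).
#' @return integer vector of node ids (always includes `node`).
#' @export
capture_nodes <- function(mesh, node, radius = 10) {
  ctr <- mesh$nodes[node, ]
  d2 <- (mesh$nodes[, 1] - ctr[1])^2 + (mesh$nodes[, 2] - ctr[2])^2 +
    (mesh$nodes[, 3] - ctr[3])^2
  which(d2 <= radius^2)
}

#' Healthy sinus-rhythm reference activation map
#'
#' Stimulates the left and right bundle entry nodes simultaneously with the
#' fast endocardial shell intact; the resulting map is the physiological
#' reference for the electrical synchrony index.
#'
#' @param mesh a `heart_mesh` with a conduction configuration.
#' @param params [monodomain_params()].
#' @return an `activation_map`.
#' @export
sinus_reference <- function(mesh, params = monodomain_params()) {
  cc <- mesh$conduction
  sts <- list(stimulus(capture_nodes(mesh, cc$left_bundle_site)),
              stimulus(capture_nodes(mesh, cc$right_bundle_site)))
  extract_activation_times(run_monodomain(mesh, params, sts))
}

#' Left-bundle-branch-block activation map
#'
#' Only the right bundle entry is stimulated at t = 0; the left bundle is
#' blocked, so the LV activates late via slow transseptal spread (the rest of
#' the fast shell stays intact and is recruited passively).
#'
#' @inheritParams sinus_reference
#' @return an `activation_map`.
#' @export
lbbb_protocol <- function(mesh, params = monodomain_params()) {
  cc <- mesh$conduction
  extract_activation_times(
    run_monodomain(mesh, params,
                   list(stimulus(capture_nodes(mesh, cc$right_bundle_site)))))
}

#' Biventricular pacing protocol
#'
#' Applies the LV lead and RV (RVA) lead stimuli with the interventricular
#' delay (VVD) sign convention: for `vvd >= 0` the LV fires at t = 0 and the
#' RV at t = vvd (LV first); for `vvd < 0` the RV fires at t = 0 and the LV
#' at t = -vvd. The intrinsic right-bundle activation of the LBBB substrate
#' also fires at t = 0. Stimuli landing in refractory tissue do not
#' re-excite (this is what saturates the index for extreme delays).
#'
#' @param mesh a `heart_mesh`.
#' @param params [monodomain_params()].
#' @param lv_node,rv_node resolved lead node ids (see
#'   [default_lead_sites()]).
#' @param vvd interventricular delay (ms), positive = LV paced first.
#' @param intrinsic logical; keep the intrinsic right-bundle activation
#'   firing at t = 0 (LBBB background conduction).
#' @param rv_enabled set `FALSE` to suppress the RV lead (for pre-emption
#'   comparisons).
#' @return an `activation_map`.
#' @export
paced_protocol <- function(mesh, params = monodomain_params(),
                           lv_node, rv_node, vvd = 0,
                           intrinsic = TRUE, rv_enabled = TRUE) {
  stopifnot(length(lv_node) == 1, length(rv_node) == 1)
  lv_on <- if (vvd >= 0) 0 else -vvd
  rv_on <- if (vvd >= 0) vvd else 0
  sts <- list(stimulus(capture_nodes(mesh, lv_node), onset = lv_on))
  if (rv_enabled)
    sts <- c(sts, list(stimulus(capture_nodes(mesh, rv_node), onset = rv_on)))
  if (intrinsic)
    sts <- c(sts, list(stimulus(
      capture_nodes(mesh, mesh$conduction$right_bundle_site), onset = 0)))
  extract_activation_times(run_monodomain(mesh, params, sts))
}
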