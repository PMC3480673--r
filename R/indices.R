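# The four outcome measures: CURE, E_RMS, DI, LVEF.

#' Zero- and first-order circumferential Fourier power of one strain ring
#'
#' For a ring of circumferential strain values at equiangular positions
#' theta_j, the zero-order power is the squared ring mean and the
#' first-order power is the squared amplitude of the first circumferential
#' harmonic, with the amplitude convention
#' a1 = |(2/N) sum_j eps_j exp(-i theta_j)|. A perfectly synchronous ring is
#' all zero-order; a pure sinusoid is all first-order.
#'
#' @param ecc numeric vector of circumferential strains (>= 4 samples,
#'   ordered by angle, equiangular).
#' @param theta optional sample angles (rad); defaults to equiangular
#'   2*pi*(j-1)/N.
#' @return named numeric vector `c(p0, p1)`.
#' @export
fourier_ring_power <- function(ecc, theta = NULL) {
  n <- length(ecc)
  if (n < 4) stop("need at least 4 circumferential samples")
  if (is.null(theta)) theta <- 2 * pi * (seq_len(n) - 1) / n
  p0 <- mean(ecc)^2
  a1 <- abs(sum(ecc * exp(-1i * theta)) * 2 / n)
  c(p0 = p0, p1 = a1^2)
}

#' Circumferential uniformity ratio estimate (CURE)
#'
#' Sums the zero- and first-order circumferential Fourier powers of the
#' ring-strain series over all slices and frames into A0^2 and A1^2, and
#' returns sqrt(A0^2 / (A0^2 + 2 A1^2)). CURE = 1 means all segments
#' contract synchronously; symmetrically dyssynchronous (pure
#' first-harmonic) contraction gives CURE = 0. Computed over LV + septum
#' samples only.
#'
#' @param series tibble with columns `slice`, `frame_ms`, `sample`, `ecc`
#'   (see [ring_strain_series()] / [make_ring_series()]).
#' @param frames optional vector of `frame_ms` values to include (e.g. the
#'   systolic frames); default all.
#' @return CURE in \[0, 1\].
#' @export
cure <- function(series, frames = NULL) {
  stopifnot(all(c("slice", "frame_ms", "sample", "ecc") %in% names(series)))
  if (!is.null(frames)) series <- dplyr::filter(series, .data$frame_ms %in% frames)
  pw <- series |>
    dplyr::arrange(.data$slice, .data$frame_ms, .data$sample) |>
    dplyr::group_by(.data$slice, .data$frame_ms) |>
    dplyr::summarise(p0 = fourier_ring_power(.data$ecc)[1],
                     p1 = fourier_ring_power(.data$ecc)[2],
                     .groups = "drop")
  a0 <- sum(pw$p0); a1 <- sum(pw$p1)
  if (a0 == 0 && a1 == 0)
    stop("CURE undefined: identically zero strain series")
  sqrt(a0 / (a0 + 2 * a1))
}

#' Electrical synchrony error E_RMS
#'
#' Root-mean-square difference between a pathological (or paced) activation
#' map and the sinus-rhythm reference over all N mesh nodes:
#' E_RMS = sqrt((1/N) sum_i (x_i - e_i)^2).
#'
#' @param pathological,reference `activation_map`s (or numeric vectors) on
#'   the same node set, fully activated.
#' @return E_RMS in ms.
#' @export
e_rms <- function(pathological, reference) {
  x <- as.numeric(reference); e <- as.numeric(pathological)
  if (length(x) != length(e))
    stop("activation maps are defined on different node sets")
  bad <- which(is.na(x) | is.na(e))
  if (length(bad) > 0)
    stop("unactivated nodes present: ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "")
  sqrt(mean((x - e)^2))
}

#' Segment-averaged strain-time traces at the equator
#'
#' Averages the maximum principal strain E1 over the samples of each LV wall
#' segment (anterior, lateral, posterior, septum) on the layer-7 ring for
#' every frame, and records each segment's time to peak strain (ties broken
#' by the earliest frame).
#'
#' @param series ring-strain series containing `e1` (from
#'   [ring_strain_series()]) including the trace layer.
#' @param layer the slice to trace (default 7).
#' @return object of class `segment_traces`: tibble with `segment`,
#'   `frame_ms`, `e1`; attribute `peaks` holds per-segment peak times.
#' @export
segment_strain_traces <- function(series, layer = 7) {
  stopifnot("e1" %in% names(series))
  sl <- dplyr::filter(series, .data$slice == layer)
  if (nrow(sl) == 0) stop("series does not contain the trace layer")
  sl$segment <- segment_of_angle(sl$theta)
  tr <- sl |>
    dplyr::group_by(.data$segment, .data$frame_ms) |>
    dplyr::summarise(e1 = mean(.data$e1), .groups = "drop") |>
    dplyr::arrange(.data$segment, .data$frame_ms)
  peaks <- tr |>
    dplyr::group_by(.data$segment) |>
    dplyr::summarise(peak_e1 = max(.data$e1),
                     t_peak = .data$frame_ms[which.max(.data$e1)],
                     .groups = "drop")
  structure(tr, peaks = peaks, class = c("segment_traces", class(tr)))
}

#' Map circumferential angles to LV wall segments
#'
#' Quadrants about the LV long axis: lateral at 0, anterior at +pi/2,
#' septum at pi, posterior at -pi/2 (each +- pi/4).
#'
#' @param theta angles in radians.
#' @return character vector of segment names.
#' @export
segment_of_angle <- function(theta) {
  d_sept <- abs(atan2(sin(theta - pi), cos(theta - pi)))
  d_lat <- abs(atan2(sin(theta), cos(theta)))
  d_ant <- abs(atan2(sin(theta - pi / 2), cos(theta - pi / 2)))
  ifelse(d_sept <= pi / 4, "septum",
  ifelse(d_lat <= pi / 4, "lateral",
  ifelse(d_ant <= pi / 4, "anterior", "posterior")))
}

#' Dyssynchrony index (DI)
#'
#' The difference in the timing of the peak strain from the earliest to the
#' latest LV wall segment.
#'
#' @param traces a `segment_traces` object (or a tibble with `segment`,
#'   `frame_ms`, `e1`).
#' @return DI in ms.
#' @export
dyssynchrony_index <- function(traces) {
  peaks <- attr(traces, "peaks")
  if (is.null(peaks)) {
    peaks <- traces |>
      dplyr::group_by(.data$segment) |>
      dplyr::summarise(peak_e1 = max(.data$e1),
                       t_peak = .data$frame_ms[which.max(.data$e1)],
                       .groups = "drop")
  }
  flat <- traces |>
    dplyr::group_by(.data$segment) |>
    dplyr::summarise(rng = diff(range(.data$e1)), .groups = "drop")
  if (any(flat$rng == 0))
    stop("flat strain trace (no peak) in segment(s): ",
         paste(flat$segment[flat$rng == 0], collapse = ", "))
  max(peaks$t_peak) - min(peaks$t_peak)
}

# signed volume of a closed triangulated surface (divergence theorem);
# positive for outward orientation.
.surface_volume <- function(vertices, triangles) {
  a <- vertices[triangles[, 1], , drop = FALSE]
  b <- vertices[triangles[, 2], , drop = FALSE]
  cc <- vertices[triangles[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) +
      a[, 2] * (b[, 3] * cc[, 1] - b[, 1] * cc[, 3]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

#' Volume enclosed by a closed triangulated surface
#'
#' Divergence-theorem volume; orientation-signed, so an inverted surface is
#' reported as an error.
#'
#' @param vertices V x 3 matrix (mm).
#' @param triangles T x 3 index matrix, outward orientation.
#' @return volume in mm^3.
#' @export
surface_volume <- function(vertices, triangles) {
  v <- .surface_volume(vertices, triangles)
  if (v <= 0) stop("inverted (negative-volume) surface")
  v
}

#' Deformed LV cavity volume
#'
#' Volume of the deformed LV endocardial surface, closed with a basal cap
#' (and the tiny apical cap of the truncated-ellipsoid idealization), via
#' the divergence theorem over surface triangles. Returns mL.
#'
#' @param mesh a `heart_mesh` built by [build_biventricular_mesh()].
#' @param displacement optional n_nodes x 3 displacement matrix (mm);
#'   default undeformed.
#' @return LV cavity volume in mL.
#' @export
cavity_volume <- function(mesh, displacement = NULL) {
  if (is.null(mesh$surfaces$lv_endo)) stop("mesh has no LV endocardial surface")
  coords <- mesh$nodes
  if (!is.null(displacement)) coords <- coords + displacement
  faces <- mesh$surfaces$lv_endo
  # stored endo quads have into-cavity normals; reverse for cavity-outward
  tris <- rbind(faces[, c(3, 2, 1)], faces[, c(4, 3, 1)])
  vol <- .surface_volume(coords, tris)
  cap_tris <- function(ring, flip) {
    ctr <- colMeans(coords[ring, , drop = FALSE])
    v <- rbind(coords, ctr)
    ic <- nrow(v)
    nr <- length(ring)
    t1 <- cbind(ring, ring[c(2:nr, 1)], ic)
    if (flip) t1 <- t1[, c(2, 1, 3)]
    .surface_volume(v, t1)
  }
  g <- mesh$geom
  vol <- vol + cap_tris(g$lv_endo_ring_base, flip = FALSE) +
    cap_tris(g$lv_endo_ring_apex, flip = TRUE)
  if (vol <= 0) stop("inverted LV endocardial surface (non-positive volume)")
  vol / 1000
}

#' Left ventricular ejection fraction
#'
#' LVEF = (EDV - ESV) / EDV. EDV is the end-diastolic (undeformed reference)
#' cavity volume; ESV the end-systolic (minimum over frames) volume.
#'
#' @param edv_ml,esv_ml volumes in mL; alternatively pass a
#'   `contraction_frames` object as `edv_ml`.
#' @return ejection fraction as a dimensionless fraction.
#' @export
lvef <- function(edv_ml, esv_ml = NULL) {
  if (inherits(edv_ml, "contraction_frames")) {
    esv_ml <- edv_ml$esv_ml
    edv_ml <- edv_ml$edv_ml
  }
  if (edv_ml <= 0) stop("EDV must be positive")
  if (esv_ml < 0) stop("ESV must be non-negative")
  (edv_ml - esv_ml) / edv_ml
}

#' Systolic frame window of a contraction
#'
#' Frames from the earliest activation to the frame of minimum cavity
#' volume (end-systole) — the window over which the CURE powers are summed.
#'
#' @param frames a `contraction_frames` object.
#' @param activation the driving `activation_map`.
#' @return numeric vector of frame times (ms).
#' @export
systolic_frames <- function(frames, activation) {
  t0 <- min(as.numeric(activation), na.rm = TRUE)
  t_es <- frames$times[which.min(frames$volume_ml)]
  frames$times[frames$times >= t0 & frames$times <= t_es]
}
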