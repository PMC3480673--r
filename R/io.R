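# Plain-text exchange formats: VTK legacy unstructured grids for meshes and
# fields, CSV for activation maps and strain series, YAML for configs.

#' Write a mesh (with optional fields) as a VTK legacy unstructured grid
#'
#' ASCII VTK legacy format with hexahedron cells, cell-data arrays for the
#' fiber components, layer index and segment label code, and optional extra
#' point/cell data. Readable by ParaView and meshio.
#'
#' @param mesh a `heart_mesh`.
#' @param path output file path (.vtk).
#' @param point_data named list of per-node numeric vectors (e.g. an
#'   activation map or displacement magnitudes).
#' @param cell_data named list of per-element numeric vectors.
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, point_data = list(), cell_data = list()) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("biventricular mesh")
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  wl("POINTS ", n, " double")
  writeLines(apply(mesh$nodes, 1, function(r) paste(format(r, digits = 10),
                                                    collapse = " ")), con)
  wl("CELLS ", m, " ", m * 9)
  writeLines(apply(mesh$elems - 1L, 1, function(r) paste(c(8, r), collapse = " ")),
             con)
  wl("CELL_TYPES ", m)
  writeLines(rep("12", m), con)

  if (!is.null(mesh$fiber)) {
    cell_data <- c(list(fiber_x = mesh$fiber[, 1], fiber_y = mesh$fiber[, 2],
                        fiber_z = mesh$fiber[, 3]), cell_data)
  }
  if (!is.null(mesh$elem$layer)) cell_data$layer <- mesh$elem$layer
  if (!is.null(mesh$elem$segment))
    cell_data$segment_code <- as.integer(factor(mesh$elem$segment))
  if (length(cell_data) > 0) {
    wl("CELL_DATA ", m)
    for (nm in names(cell_data)) {
      wl("SCALARS ", nm, " double 1")
      wl("LOOKUP_TABLE default")
      writeLines(format(as.numeric(cell_data[[nm]]), digits = 10), con)
    }
  }
  if (length(point_data) > 0) {
    wl("POINT_DATA ", n)
    for (nm in names(point_data)) {
      wl("SCALARS ", nm, " double 1")
      wl("LOOKUP_TABLE default")
      writeLines(format(as.numeric(point_data[[nm]]), digits = 10), con)
    }
  }
  invisible(path)
}

#' Write an activation map as CSV
#'
#' Columns `node_id`, `t_act_ms` (empty for unactivated nodes).
#'
#' @param map an `activation_map`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_activation_csv <- function(map, path) {
  utils::write.csv(tidy.activation_map(map), path, row.names = FALSE)
  invisible(path)
}

#' Write a ring-strain series (or segment traces) as CSV
#' @param series a tibble (e.g. from [ring_strain_series()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_strain_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' Read a structured simulation config file
#'
#' YAML with the sections `mesh`, `fibers`, `conduction`, `electrics`,
#' `mechanics`, `material`, `sweep`; all keys optional, merged over the
#' package defaults. Returns ready-to-use parameter objects.
#'
#' @param path YAML file path.
#' @return list with `mesh_spec`, `fiber_angles`, `conduction`,
#'   `monodomain_params`, `material_params`, `twitch_params`, `base_spring`,
#'   `sweep_grid`.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  take <- function(defaults, section) {
    user <- cfg[[section]] %||% list()
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown) > 0)
      stop("unknown config key(s) in [", section, "]: ",
           paste(unknown, collapse = ", "))
    utils::modifyList(defaults, user)
  }
  ms <- do.call(mesh_spec, take(formals_defaults(mesh_spec), "mesh"))
  fib <- take(list(endo_angle_deg = 60, epi_angle_deg = -60), "fibers")
  cond <- take(list(fast_shell_multiplier = 6, lbbb = TRUE), "conduction")
  ep <- do.call(monodomain_params,
                take(formals_defaults(monodomain_params), "electrics"))
  mat <- do.call(material_params,
                 take(formals_defaults(material_params), "material"))
  mech <- take(list(tmax_kpa = 10, t_rise_ms = 60, t_decay_ms = 80,
                    duration_ms = 400, frame_ms = 10, base_spring = 50),
               "mechanics")
  tw <- twitch_params(mech$tmax_kpa, mech$t_rise_ms, mech$t_decay_ms,
                      mech$duration_ms)
  swd <- take(list(lv_sites = c("POST-B", "POST-E", "LAT-B", "LAT-E",
                                "ANT-B", "ANT-E"),
                   vvd_values = seq(-72, 72, by = 12)), "sweep")
  list(mesh_spec = ms,
       fiber_angles = c(fib$endo_angle_deg, fib$epi_angle_deg),
       conduction = cond,
       monodomain_params = ep,
       material_params = mat,
       twitch_params = tw,
       frame_ms = mech$frame_ms,
       base_spring = mech$base_spring,
       sweep_grid = sweep_grid(swd$lv_sites, swd$vvd_values))
}

# default formal arguments of a function as an evaluated list
formals_defaults <- function(fn) {
  fm <- formals(fn)
  fm <- fm[!vapply(fm, is.symbol, logical(1))]
  lapply(fm, eval, envir = baseenv())
}
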