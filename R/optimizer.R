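# Pacing-configuration sweep and optimum selection.

#' Sweep grid of pacing configurations
#'
#' The default grid is the 6 LV epicardial lead sites crossed with 13
#' interventricular delays (-72 to +72 ms in steps of 12), i.e. 78
#' configurations, with the RV lead fixed at the RV apex.
#'
#' @param lv_sites character vector of LV lead-site names.
#' @param vvd_values interventricular delays (ms), sorted ascending;
#'   positive = LV stimulated first.
#' @param rv_site RV lead-site name.
#' @return object of class `sweep_grid`.
#' @export
sweep_grid <- function(lv_sites = c("POST-B", "POST-E", "LAT-B", "LAT-E",
                                    "ANT-B", "ANT-E"),
                       vvd_values = seq(-72, 72, by = 12),
                       rv_site = "RVA") {
  if (length(lv_sites) == 0 || length(vvd_values) == 0)
    stop("empty sweep grid")
  structure(list(lv_sites = lv_sites, vvd_values = sort(vvd_values),
                 rv_site = rv_site), class = "sweep_grid")
}

#' Enumerate the pacing configurations of a grid
#'
#' Cartesian product in deterministic order: site-major, VVD ascending
#' within each site.
#'
#' @param grid a [sweep_grid()].
#' @return tibble with `config_id`, `lv_site`, `vvd_ms`, `rv_site`.
#' @export
enumerate_configs <- function(grid = sweep_grid()) {
  if (!inherits(grid, "sweep_grid")) stop("grid must be a sweep_grid")
  out <- tidyr::expand_grid(lv_site = grid$lv_sites, vvd_ms = grid$vvd_values)
  out$rv_site <- grid$rv_site
  out$config_id <- sprintf("%s/%+04d", out$lv_site, out$vvd_ms)
  dplyr::select(out, "config_id", "lv_site", "vvd_ms", "rv_site")
}

#' Run the full electromechanical pipeline for one pacing configuration
#'
#' Paced activation map, contraction frames, equatorial ring-strain series,
#' and the four indices (CURE over the systolic window, E_RMS against the
#' sinus reference, DI at layer 7, LVEF). Deterministic given its inputs.
#'
#' @param mesh a `heart_mesh`.
#' @param eparams [monodomain_params()].
#' @param lv_site,vvd_ms configuration (LV site name, delay in ms); use
#'   `lv_site = NA` for the unpaced LBBB baseline and `lv_site = "sinus"`
#'   for the sinus reference record.
#' @param sites lead-site catalogue from [default_lead_sites()].
#' @param reference sinus `activation_map` for E_RMS.
#' @param material,twitch,base_spring mechanics settings.
#' @param sys pre-assembled mechanics system (recommended for sweeps).
#' @param layers,n_points CURE slices and circumferential sampling.
#' @return one-row tibble: `config_id`, `lv_site`, `vvd_ms`, `cure`,
#'   `e_rms_ms`, `di_ms`, `lvef`, `edv_ml`, `esv_ml`, `status`.
#' @export
run_config <- function(mesh, eparams, lv_site, vvd_ms, sites, reference,
                       material = material_params(), twitch = twitch_params(),
                       base_spring = 50, sys = NULL,
                       layers = 6:9, n_points = 30) {
  cid <- if (is.na(lv_site)) "LBBB"
         else if (identical(lv_site, "sinus")) "sinus"
         else sprintf("%s/%+04d", lv_site, vvd_ms)
  rec <- tibble::tibble(config_id = cid, lv_site = lv_site, vvd_ms = vvd_ms,
                        cure = NA_real_, e_rms_ms = NA_real_, di_ms = NA_real_,
                        lvef = NA_real_, edv_ml = NA_real_, esv_ml = NA_real_,
                        status = "ok")
  out <- tryCatch({
    map <- if (is.na(lv_site)) {
      lbbb_protocol(mesh, eparams)
    } else if (identical(lv_site, "sinus")) {
      reference
    } else {
      lvn <- sites$node_id[sites$name == lv_site]
      rvn <- sites$node_id[sites$name == "RVA"]
      if (length(lvn) != 1) stop("unresolved LV site: ", lv_site)
      paced_protocol(mesh, eparams, lvn, rvn, vvd = vvd_ms)
    }
    fr <- simulate_contraction(mesh, map, material, twitch,
                               base_spring = base_spring, sys = sys)
    rs <- ring_strain_series(mesh, fr, layers = layers, n_points = n_points)
    sf <- systolic_frames(fr, map)
    tr <- segment_strain_traces(rs, layer = layers[min(2, length(layers))])
    rec$cure <- cure(rs, sf)
    rec$e_rms_ms <- e_rms(map, reference)
    rec$di_ms <- dyssynchrony_index(tr)
    rec$lvef <- lvef(fr)
    rec$edv_ml <- fr$edv_ml
    rec$esv_ml <- fr$esv_ml
    rec
  }, error = function(e) {
    rec$status <- paste0("failed: ", conditionMessage(e))
    rec
  })
  out
}

#' Sweep all pacing configurations and select the optima
#'
#' Runs [run_config()] for the sinus reference, the LBBB baseline, and every
#' configuration of the grid, then selects the optimum under both the
#' mechanical (max CURE) and electrical (min E_RMS) strategy.
#'
#' @param mesh a `heart_mesh`.
#' @param grid a [sweep_grid()].
#' @param eparams [monodomain_params()].
#' @param material,twitch,base_spring mechanics settings.
#' @param layers,n_points CURE slices and sampling.
#' @param progress print one line per configuration.
#' @return a `sync_report`: tibble of per-configuration records with
#'   attributes `baselines` (sinus + LBBB rows) and `optima`.
#' @export
run_sweep <- function(mesh, grid = sweep_grid(),
                      eparams = monodomain_params(),
                      material = material_params(), twitch = twitch_params(),
                      base_spring = 50, layers = 6:9, n_points = 30,
                      progress = FALSE) {
  sites <- default_lead_sites(mesh)
  sys <- assemble_global(mesh, material, base_spring)
  reference <- sinus_reference(mesh, eparams)
  base_args <- list(mesh = mesh, eparams = eparams, sites = sites,
                    reference = reference, material = material,
                    twitch = twitch, base_spring = base_spring, sys = sys,
                    layers = layers, n_points = n_points)
  sinus_rec <- do.call(run_config, c(base_args, lv_site = "sinus", vvd_ms = NA))
  lbbb_rec <- do.call(run_config, c(base_args, lv_site = NA, vvd_ms = NA))
  cfgs <- enumerate_configs(grid)
  recs <- purrr::pmap(list(cfgs$lv_site, cfgs$vvd_ms), function(s, v) {
    if (progress) message(sprintf("config %s / %+d ms", s, v))
    do.call(run_config, c(base_args, list(lv_site = s, vvd_ms = v)))
  })
  records <- dplyr::bind_rows(recs)
  baselines <- dplyr::bind_rows(sinus_rec, lbbb_rec)
  optima <- dplyr::bind_rows(
    dplyr::mutate(select_optimum(records, "mechanical"), strategy = "mechanical"),
    dplyr::mutate(select_optimum(records, "electrical"), strategy = "electrical"))
  structure(records, baselines = baselines, optima = optima,
            class = c("sync_report", class(records)))
}

#' Select the optimal configuration under a strategy
#'
#' Mechanical strategy: maximize CURE. Electrical strategy: minimize E_RMS.
#' Ties are broken by smaller |VVD| (simpler device programming), then by
#' catalogue order.
#'
#' @param records tibble of configuration records (columns `cure`,
#'   `e_rms_ms`, `vvd_ms`, `status`).
#' @param strategy `"mechanical"` or `"electrical"`.
#' @return the optimal record (one-row tibble).
#' @export
select_optimum <- function(records, strategy = c("mechanical", "electrical")) {
  strategy <- match.arg(strategy)
  ok <- dplyr::filter(records, .data$status == "ok")
  if (nrow(ok) == 0) stop("all configurations failed; no optimum")
  score <- if (strategy == "mechanical") ok$cure else -ok$e_rms_ms
  best <- max(score)
  cand <- which(score == best)
  if (length(cand) > 1) cand <- cand[order(abs(ok$vvd_ms[cand]), cand)][1]
  ok[cand[1], ]
}

#' @export
print.sync_report <- function(x, ...) {
  cat("<sync_report> ", nrow(x), " pacing configurations\n", sep = "")
  b <- attr(x, "baselines")
  if (!is.null(b)) {
    lb <- b[b$config_id == "LBBB", ]
    cat(sprintf("  LBBB baseline: CURE %.4f, E_RMS %.2f ms, DI %.0f ms, LVEF %.1f%%\n",
                lb$cure, lb$e_rms_ms, lb$di_ms, 100 * lb$lvef))
  }
  o <- attr(x, "optima")
  if (!is.null(o)) for (i in seq_len(nrow(o)))
    cat(sprintf("  %s optimum: %s (CURE %.4f, E_RMS %.2f ms, LVEF %.1f%%)\n",
                o$strategy[i], o$config_id[i], o$cure[i], o$e_rms_ms[i],
                100 * o$lvef[i]))
  cat("\n")
  NextMethod()
}

#' Tidy the per-configuration records of a sweep
#' @param x a `sync_report`.
#' @param ... unused.
#' @return plain tibble of records.
#' @exportS3Method generics::tidy
tidy.sync_report <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a sweep: baselines and both optima
#' @param x a `sync_report`.
#' @param ... unused.
#' @return one-row tibble.
#' @exportS3Method generics::glance
glance.sync_report <- function(x, ...) {
  b <- attr(x, "baselines"); o <- attr(x, "optima")
  lb <- b[b$config_id == "LBBB", ]
  om <- o[o$strategy == "mechanical", ]; oe <- o[o$strategy == "electrical", ]
  tibble::tibble(
    n_configs = nrow(x), n_failed = sum(x$status != "ok"),
    lbbb_cure = lb$cure, lbbb_e_rms_ms = lb$e_rms_ms, lbbb_lvef = lb$lvef,
    best_cure = om$cure, best_cure_config = om$config_id,
    best_cure_lvef = om$lvef,
    min_e_rms_ms = oe$e_rms_ms, min_e_rms_config = oe$config_id,
    min_e_rms_lvef = oe$lvef)
}
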