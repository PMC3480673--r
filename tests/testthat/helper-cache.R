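# Shared, lazily built simulation fixtures. The electromechanical runs are
# deterministic, so heavy objects (heart mesh, activation maps, contraction
# frames) are computed once per session and reused across test files.

.crtsim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .crtsim_cache)) {
    assign(key, force(expr), envir = .crtsim_cache)
  }
  get(key, envir = .crtsim_cache)
}

# coarse biventricular mesh used by all whole-heart tests
test_spec <- function() {
  mesh_spec(n_circumferential = 24, n_transmural = 2, n_transmural_rv = 1)
}

test_heart <- function() cached("heart", build_biventricular_mesh(test_spec()))

test_eparams <- function() monodomain_params()

test_sites <- function() cached("sites", default_lead_sites(test_heart()))

test_sinus <- function() cached("sinus", sinus_reference(test_heart(), test_eparams()))

test_lbbb <- function() cached("lbbb", lbbb_protocol(test_heart(), test_eparams()))

test_mech_sys <- function() cached("mech_sys", assemble_global(test_heart()))

test_paced <- function(vvd, site = "LAT-E", rv_enabled = TRUE) {
  key <- sprintf("paced_%s_%d_%d", site, vvd, rv_enabled)
  cached(key, {
    s <- test_sites()
    paced_protocol(test_heart(), test_eparams(),
                   s$node_id[s$name == site], s$node_id[s$name == "RVA"],
                   vvd = vvd, rv_enabled = rv_enabled)
  })
}

# full per-configuration record (indices) on the coarse heart
test_record <- function(lv_site, vvd) {
  key <- sprintf("rec_%s_%s", lv_site, vvd)
  cached(key, {
    run_config(test_heart(), test_eparams(), lv_site, vvd,
               sites = test_sites(), reference = test_sinus(),
               sys = test_mech_sys())
  })
}

test_contraction <- function(map_key) {
  key <- paste0("contr_", map_key)
  map <- switch(map_key, lbbb = test_lbbb(), sinus = test_sinus())
  cached(key, simulate_contraction(test_heart(), map, sys = test_mech_sys()))
}
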