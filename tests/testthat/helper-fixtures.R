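# Shared fixtures, built once per test run. The "tiny" head uses coarse
# meshes (642 vertices per cortical surface) so that inversions run in well
# under a second; the geometry defaults (radii, 2 mm layer separation, bump
# pattern) are the package defaults.

.fixture_env <- new.env()

tiny_head <- function() {
  if (is.null(.fixture_env$head)) {
    geo <- make_head_geometry(subdivisions = 3, seed = 1)
    geo$space$white <- opmlaminar:::cache_mesh_graph(geo$space$white)
    geo$space$pial <- opmlaminar:::cache_mesh_graph(geo$space$pial)
    geo$space$mid <- opmlaminar:::cache_mesh_graph(geo$space$mid)
    .fixture_env$head <- geo
  }
  .fixture_env$head
}

tiny_array <- function(n_axes = 1, offset = 6.5, min_distance = 55) {
  geo <- tiny_head()
  arr <- pack_sensors(geo$scalp, min_distance, seed = 3)
  arr <- build_channel_axes(arr, n_axes)
  offset_sensors(arr, geo$scalp, offset)
}

tiny_conductor <- function(arr = tiny_array()) {
  opmlaminar:::default_conductor(tiny_head()$space, arr)
}

tiny_setup <- function() {
  if (is.null(.fixture_env$setup)) {
    arr <- tiny_array()
    .fixture_env$setup <- laminar_setup(tiny_head()$space, arr, tiny_conductor(arr))
  }
  .fixture_env$setup
}

# a noisy single-source dataset on the tiny head
tiny_dataset <- function(surface = "pial", v0 = 123, snr_db = -5,
                         n_trials = 30, seed = 11) {
  setup <- tiny_setup()
  patch <- suppressWarnings(gaussian_patch(tiny_head()$space[[surface]], v0, 5))
  ds <- simulate_signal(patch, setup$leadfields[[surface]], n_trials = n_trials,
                        surface = surface)
  add_noise(ds, snr_spec("per_trial_snr", snr_db), seed = seed)
}
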