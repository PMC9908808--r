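# Shared default worlds, generated once per test run. The noiseless world is
# the reference condition for exact-recovery checks.
.world_cache <- new.env(parent = emptyenv())

cached_world <- function(noiseless = FALSE) {
  key <- if (noiseless) "w0" else "w"
  if (is.null(.world_cache[[key]])) {
    cfg <- if (noiseless) sim_config(seed = 101, fluor_cv = 0, titer_cv = 0)
      else sim_config(seed = 101)
    .world_cache[[key]] <- generate_genome(cfg)
  }
  .world_cache[[key]]
}

cached_plate <- function(noiseless = FALSE) {
  key <- if (noiseless) "p0" else "p"
  if (is.null(.world_cache[[key]])) {
    w <- cached_world(noiseless)
    .world_cache[[key]] <- generate_plate_reader(w, w$config)
  }
  .world_cache[[key]]
}
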