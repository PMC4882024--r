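# Lazily-built shared world for the acceptance tests: one synthetic terrain
# with soils, kriged 7-variable environment stack and habitat map. Building
# it costs a few seconds, so it is cached across test blocks.
.world_cache <- new.env(parent = emptyenv())

acceptance_world <- function() {
  if (!exists("world", envir = .world_cache)) {
    terr <- make_terrain(seed = 424242)
    soils <- make_soils(terr, seed = 424243)
    prep <- suppressWarnings(
      prepare_environment(terr$posts, soils$samples, terr$window))
    assign("world", list(terr = terr, soils = soils, env = prep$env,
                         habitat_map = prep$habitat_map),
           envir = .world_cache)
  }
  get("world", envir = .world_cache)
}
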