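# Shared fixtures, built lazily and memoized across test files.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

its1_far <- function() fixture("its1_far", function()
  assemble_system(build_its1(), simulation_config(), "far"))

its1_far_map <- function() fixture("its1_far_map", function()
  compute_wavefront(its1_far(), n_grid = 64))

# a well-corrected low-aperture fixture: single refracting sphere used far
# inside the paraxial regime
ideal_fixture <- function() fixture("ideal", function()
  make_single_sphere(20, 1.5, semi_diameter = 0.25))
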