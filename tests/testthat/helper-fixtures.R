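# Small phantoms shared across test files, built once per run.
# Coarse voxels keep registration matrices tiny; planted geometry stays exact.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# 3-segment wild-type-like phantom at 1.1 um voxels, light noise
tiny_params <- function(...) {
  defaults <- list(n_segments = 3, voxel_pitch = 1.1,
                   cross_section = c(24, 16), noise_gaussian_sd = 1, seed = 7)
  do.call(phantom_params, utils::modifyList(defaults, list(...)))
}

tiny_phantom <- function() cached("tiny", generate_phantom(tiny_params()))

# noiseless variant: deterministic rendering only
quiet_params <- function(...) {
  tiny_params(noise_gaussian_sd = 0, noise_poisson = FALSE, ...)
}

quiet_phantom <- function() cached("quiet", generate_phantom(quiet_params()))

# one transverse section of the noiseless phantom, taken at a node
quiet_node_section <- function() {
  ph <- quiet_phantom()
  i <- round(ph$truth$node_positions[2] / ph$volume$pitch[["ap"]])
  ph$volume$intensities[i, , ]
}

# synthetic cosine trace on a bin grid
cosine_trace <- function(period = 28, bin = 1.65, n = 60, amplitude = 0.3,
                         level = 0.6, phase = 0) {
  pos <- (seq_len(n) - 0.5) * bin
  node_trace(position = pos,
             value = level + amplitude * cos(2 * pi * (pos - phase) / period),
             bin_length = bin)
}
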