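# Internal interpolation front-end over the compiled samplers.

interpCode <- function(interpolation) {
  switch(match.arg(interpolation, c("nearest", "linear", "cubic_spline")),
         nearest = 0L, linear = 1L, cubic_spline = 2L)
}

# Sample a ScalarVolume at fractional 0-based voxel coordinates of its own
# grid.  Returns list(values, valid); values are 0 where invalid.
sampleAtVoxels <- function(vol, vox, interpolation = "linear",
                           useFov = TRUE) {
  code <- interpCode(interpolation)
  fov <- if (useFov) vol@fov else numeric(0)
  cpp_sample(vol@values, fov, vox, code)
}

# Sample a plain array (no FOV semantics); out-of-grid -> 0, invalid.
sampleArrayAtVoxels <- function(arr, vox, interpolation = "linear") {
  cpp_sample(arr, numeric(0), vox, interpCode(interpolation))
}
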