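# Shared fixtures: compact phantom configurations built in code.

tiny_geometry <- function() {
  phantom_geometry(matrix_size = 32, pixel_mm = 110 / 32)
}

tiny_config <- function(mode = "velocity_selective", seed = 1L, n_frames = 20,
                        noise_sigma = 0, psf_fwhm_px = 0, ...) {
  phantom_config(
    geometry = tiny_geometry(),
    protocol = acquisition_protocol(mode = mode, seed = seed,
                                    n_frames = n_frames,
                                    noise_sigma = noise_sigma,
                                    psf_fwhm_px = psf_fwhm_px, ...)
  )
}

default_config <- function(mode = "velocity_selective", seed = 1L, ...) {
  phantom_config(protocol = acquisition_protocol(mode = mode, seed = seed, ...))
}
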