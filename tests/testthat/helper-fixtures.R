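# Shared fixtures: one default library per run, the reference lung weight
# vector, and a shorthand for synthetic ensembles.

default_lib <- make_library()

lung_truth <- rabbit_lung_weights()

synth_pairs <- function(weights = lung_truth, noise_sd = 0, n_samples = 1,
                        seed = 1, background_mua = 0, thickness_cm = 0.05,
                        lib = default_lib) {
  synth_measurements(lib, synth_config(weights, thickness_cm = thickness_cm,
                                       noise_sd = noise_sd,
                                       n_samples = n_samples, seed = seed,
                                       background_mua = background_mua))
}

# independent two-point linear interpolation oracle (no approx())
interp_oracle <- function(x, y, xout) {
  vapply(xout, function(x0) {
    if (x0 <= x[1]) return(y[1])
    i <- max(which(x <= x0))
    if (i == length(x)) return(y[length(y)])
    t <- (x0 - x[i]) / (x[i + 1] - x[i])
    (1 - t) * y[i] + t * y[i + 1]
  }, numeric(1))
}
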