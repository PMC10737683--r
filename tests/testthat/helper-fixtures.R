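# Shared fixtures: a mid-sized reference patient and a deterministic way to
# draw plausible random kinetic parameter sets.

ref_vols <- function() split_volumes(40) # v1:v2:v3 = 10/3, 10, 80/3 L

random_param_sets <- function(n, seed = 101) {
  withr::with_seed(seed, {
    tibble::tibble(
      tbw = runif(n, 25, 55),
      k1 = exp(runif(n, log(5), log(100))),
      k2 = exp(runif(n, log(1), log(30))),
      kd = runif(n, 6.5, 11.5),
      c0 = runif(n, 0.8, 2.4),
      duration = sample(c(180, 210, 240, 270), n, replace = TRUE),
      post = sample(c(0, 120), n, replace = TRUE)
    )
  })
}

# Noise-free measured plasma series for a known truth, via the generator.
noise_free_series <- function(patient) {
  generate_treatment(patient, week = 1, cv = 0, seed = 1)
}
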