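# shared fixtures: small, deterministic, built in code

# noise-free, jitter-free specimen used wherever exact identities are checked
clean_params <- function(...) {
  specimen_params(noise_sd = 0, ...)
}

# purely elastic specimen with modulus E (no drift, no loop, no stiffening)
elastic_params <- function(E = 5) {
  specimen_params(elastic_modulus_ref = E, rate_stiffening_exponent = 0,
                  stress_stiffening_exponent = 0, drift_params = NULL,
                  hysteresis_width = 0, noise_sd = 0)
}

sheep_geometry <- function() specimen_geometry(area = 394, height = 3.98)

# pure-model ratcheting curve at stress e_r with the default coefficients
model_curve <- function(e_r, n = 400, params = urmk_params()) {
  N <- seq_len(n)
  ratcheting_curve(N, urmk_evaluate(N, e_r, params),
                   stress_variation = e_r, stress_rate = 0.59)
}
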