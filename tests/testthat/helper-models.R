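# Shared fixtures: a small architecture that keeps the compiled model fast
# enough for unit tests, plus cached tiny datasets.

tiny_arch <- function(n_classes = 2, n_subjects = 4, latent = 8,
                      hemi = "both", pool = 2) {
  arch_config(latent_dim = latent, n_classes = n_classes,
              n_subjects = n_subjects, input = c(3, 64, 32),
              enc_channels = c(2, 4, 4), enc_strides = c(4, 2, 2),
              enc_dense = 16, ext_channels = c(4, 4), ext_dense = 16,
              head_dense = c(16, 16, 8), hemi = hemi, pool = pool)
}

# the scaled-down experiment architecture used throughout the heavier tests
small_arch <- function(n_classes = 2, n_subjects = 8, hemi = "both") {
  arch_config(latent_dim = 16, n_classes = n_classes, n_subjects = n_subjects,
              input = c(3, 64, 32), enc_channels = c(4, 8, 8),
              enc_strides = c(2, 2, 2), enc_dense = 64,
              ext_channels = c(8, 8), ext_dense = 32,
              head_dense = c(32, 32, 16), hemi = hemi, pool = 2)
}

small_schedules <- function(beta_max = 0.05, lambda_max = 1) {
  schedule_config(beta_max = beta_max, beta_ramp_epochs = 40,
                  lambda_max = lambda_max, lambda_ramp_epochs = 20)
}

the_fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(the_fixture_cache[[key]]))
    the_fixture_cache[[key]] <- force(expr)
  the_fixture_cache[[key]]
}

tiny_dataset <- function(seed = 7, n_subjects = 4, samples = 24) {
  cached(sprintf("ds_%d_%d_%d", seed, n_subjects, samples),
         generate_topographs(synthetic_spec(
           n_subjects = n_subjects, samples_per_subject = samples,
           seed = seed)))
}

# batch matrices for direct compiled-layer tests
tiny_batch <- function(n = 8, seed = 5) {
  withr::with_seed(seed, list(
    xl = matrix(stats::runif(3 * 64 * 32 * n), ncol = n),
    xr = matrix(stats::runif(3 * 64 * 32 * n), ncol = n),
    y = sample(0:1, n, replace = TRUE),
    s = rep_len(0:3, n)))
}

param_hash <- function(params, pattern = NULL) {
  nm <- names(params)
  if (!is.null(pattern)) nm <- grep(pattern, nm, value = TRUE)
  vapply(params[nm], function(m) sum(m) + sum(m^2), 0)
}
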