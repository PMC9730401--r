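# Shared fixtures, generated in code. Slow-to-build objects are cached per
# test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small random blob-ish binary mask
rand_mask <- function(dims, p = 0.2) {
  array(rbinom(prod(dims), 1, p), dims)
}

# connected random blob: ellipsoid with jittered center/radii
rand_blob <- function(dims, seed) {
  set.seed(seed)
  ctr <- dims * runif(3, 0.3, 0.7)
  semi <- dims * runif(3, 0.15, 0.35)
  arr <- array(0, dims)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) for (k in seq_len(dims[3])) {
    if (((i - ctr[1]) / semi[1])^2 + ((j - ctr[2]) / semi[2])^2 +
        ((k - ctr[3]) / semi[3])^2 <= 1) arr[i, j, k] <- 1
  }
  arr
}

tiny_grid_spec <- function(seed = 1L, laterality = "both", noise_sd = 0.02) {
  phantom_spec(grid_shape = c(4L, 32L, 32L), spacing = c(5, 0.8, 0.8),
               laterality = laterality, noise_sd = noise_sd, seed = seed)
}

small_spec <- function(seed = 1L, laterality = "both", ...) {
  phantom_spec(preset = "small", laterality = laterality, seed = seed, ...)
}

tiny_cohort <- function(n = 4L) {
  cached(sprintf("tiny_cohort_%d", n), {
    lapply(seq_len(n), function(i) {
      s <- tiny_grid_spec(seed = 500L + i)
      generate_phantom(s, sprintf("tiny%02d", i))
    })
  })
}

tiny_model_config <- function(in_channels = 3L) {
  model_config(in_channels = in_channels, input_size = 32L, depth = 2L,
               base_filters = 4L, encoder_block_allocation = c(1L, 1L, 1L))
}

quick_train_config <- function(epochs = 1L, seed = 11L) {
  train_config(learning_rate = 1e-3, epochs = epochs, batch_size = 8L,
               folds = 2L, seed = seed)
}
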