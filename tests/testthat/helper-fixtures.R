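# Shared fixtures, built in code at test time.

BONN_FS <- 173.61

# A pure tone segment.
tone <- function(freq, fs = BONN_FS, n = 1024, amplitude = 1) {
  amplitude * sin(2 * pi * freq * (0:(n - 1)) / fs)
}

# Write a Bonn-dialect ASCII record to a temp file and return the path.
write_bonn_fixture <- function(values) {
  path <- tempfile("bonn", fileext = ".txt")
  writeLines(as.character(values), path)
  path
}

# Small labelled table with three informative features among noise.
small_table <- function(n = 150, d = 8, effect = 1.2, seed = 5) {
  gen_feature_table(synth_table_spec(n_samples = n, n_features = d,
                                     informative_idx = 1:3,
                                     effect_size = effect, seed = seed))
}

# Fast swarm settings for unit tests.
fast_swarm <- function(seed = 3, ...) {
  swarm_config(n_particles = 10, max_iters = 10, seed = seed,
               fitness = fitness_spec(folds = 3, num_trees = 60),
               stall_window = 8, ...)
}

# Perfectly separable three-class feature matrix.
separable_features <- function(n_per_class = 20, seed = 11) {
  set.seed(seed)
  n <- 3 * n_per_class
  cls <- rep(c("c1", "c2", "c3"), each = n_per_class)
  x <- cbind(f1 = as.integer(factor(cls)) * 10 + rnorm(n, sd = 0.1),
             f2 = rnorm(n))
  feature_matrix(x, cls)
}
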