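# Shared fixtures, computed once per test run.

.fixtures <- new.env(parent = emptyenv())

# Well-separated two-class data and a 2-LV model on it.
std_data <- function() {
  if (is.null(.fixtures$data)) {
    .fixtures$data <- generate_two_class(n_per_class = 60, p = 6, delta = 6,
                                         noise_sd = 1, seed = 101)
  }
  .fixtures$data
}

std_model <- function() {
  if (is.null(.fixtures$model)) {
    .fixtures$model <- suppressMessages(
      fit_with_outlier_removal(std_data(), a = 2))
  }
  .fixtures$model
}

std_spec <- function() {
  if (is.null(.fixtures$spec)) {
    .fixtures$spec <- build_class_model(std_model(), std_data())
  }
  .fixtures$spec
}

# Random full-column-rank regression instance for oracle comparisons.
random_instance <- function(seed, n = 10, p = 4) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  X <- scale(X)
  y <- drop(scale(rnorm(n)))
  list(X = X, y = y)
}

# Printed case-study distributions used across threshold tests.
rioja_normal <- function() dist_normal(-0.95, 0.45)
rioja_triangular <- function() dist_triangular(-0.57, 1.16, 1.17)
pellets_adequate <- function() dist_normal(0.42, 0.48)
pellets_poor <- function() dist_normal(-1.01, 0.49)
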