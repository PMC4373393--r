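# Report every failure instead of aborting the run at the default cap, so
# one failing reference-value block cannot mask the rest of the suite.
options(testthat.max_fails = Inf, testthat.progress.max_fails = 1000)
Sys.setenv(TESTTHAT_MAX_FAILS = "1000")

# Shared fixtures, built lazily and cached for the whole test run. The
# "benchmark" objects are the scaled-down study conditions (2,000 train /
# 500 test synthetic digits, 64 units per model) used by the acceptance
# tests and by the trained-model property tests.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

bench_train <- function() fixture("bench_train", function()
  generate_digits(2000, seed = 101))

bench_test <- function() fixture("bench_test", function()
  generate_digits(500, seed = 102))

bench_pp <- function() fixture("bench_pp", function()
  fit_preprocessor(bench_train()))

bench_train_inputs <- function() fixture("bench_train_inputs", function()
  preprocess(bench_pp(), bench_train()))

bench_clean_test <- function() fixture("bench_clean_test", function()
  preprocess(bench_pp(), bench_test()))

# occluded test inputs on the quick grid, same occlusion RNG for all models
bench_grid <- function() fixture("bench_grid", function()
  occlusion_grid_inputs(bench_pp(), bench_test(), c(0, 0.2, 0.4), seed = 99))

bench_fastica <- function() fixture("bench_fastica", function()
  fastica(bench_train_inputs()$X, 64, seed = 201))

bench_nmfsc <- function(s_y = 0.85) {
  key <- paste0("bench_nmfsc_", s_y)
  fixture(key, function()
    nmfsc(bench_train_inputs()$X, 64, s_y = s_y, max_epochs = 100,
          seed = 202))
}

bench_pcbc <- function() fixture("bench_pcbc", function()
  pcbc(bench_train_inputs()$X, 64, n_presentations = 20000, seed = 203))

bench_hnn <- function() fixture("bench_hnn", function()
  hnn(bench_train_inputs()$X, 64, n_presentations = 100000, seed = 204))

# a tiny input set for fast model unit tests
tiny_inputs <- function() fixture("tiny_inputs", function() {
  b <- generate_digits(300, seed = 301)
  pp <- fit_preprocessor(b)
  preprocess(pp, b)
})

# Amari index of a permutation-scaling matrix P = W %*% A: 0 iff P is a
# scaled permutation, i.e. the sources were perfectly unmixed.
amari_index <- function(P) {
  P <- abs(P)
  n <- nrow(P)
  (sum(rowSums(P) / apply(P, 1, max) - 1) +
      sum(colSums(P) / apply(P, 2, max) - 1)) / (2 * n * (n - 1))
}

col_sparseness <- function(Y) {
  apply(abs(Y), 2, function(v) if (all(v == 0)) NA_real_
        else hoyer_sparseness(v))
}
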