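test_that("cosine stability is 1 at zero occlusion and scale invariant", {
  fit <- bench_fastica()
  clean <- bench_clean_test()
  expect_equal(cosine_stability(fit, clean, clean), 1)
  # invariance of the cosine to global positive rescaling of activities
  Y <- predict(fit, clean$X[, 1:50])
  cosines <- sapply(1:50, function(j) {
    a <- Y[, j]
    sum(a * (3 * a)) / sqrt(sum(a^2) * sum((3 * a)^2))
  })
  expect_equal(cosines, rep(1, 50))
})

test_that("zero codes contribute zero cosine by convention", {
  m <- bench_nmfsc(0.85)
  z <- list(X = matrix(0, 288, 3), labels = c(0L, 1L, 2L))
  expect_equal(cosine_stability(m, z, z), 0)
})

test_that("mean code sparseness is 1 for one-hot codes", {
  # a model whose codes are one-hot: NMFSC at s_y = 1
  m <- bench_nmfsc(0.85)
  m$s_y <- 1
  X <- bench_train_inputs()$X[, 1:30]
  Y <- predict(m, X)
  expect_true(all(colSums(Y > 0) == 1))
  expect_equal(mean_code_sparseness(m, list(X = X)), 1)
})

test_that("accuracy at level zero equals accuracy on the untouched test set", {
  tin <- bench_train_inputs()
  grid0 <- list(`0` = bench_clean_test())
  acc_a <- accuracy_curve(NULL, tin, grid0)
  acc_b <- accuracy_curve(NULL, tin, bench_grid()[1])
  expect_equal(unname(acc_a), unname(acc_b))
})

test_that("weight images recombine on/off and scale symmetrically", {
  on <- runif(144); off <- on
  w <- weight_image(on, off)
  expect_true(all(w == 0))                      # on = off: uniformly gray
  off2 <- numeric(144)
  w2 <- weight_image(on, off2)
  expect_equal(as.vector(w2), on)               # off = 0: the on weights
  expect_equal(attr(w2, "zmax"), max(abs(on)))  # symmetric display range
})

test_that("random-dot probes have exactly 90 foreground pixels", {
  fit <- bench_fastica()
  # intercept the probes via a unit map: just rebuild them the same way the
  # RF estimator does and check the invariant directly
  rf <- reverse_correlation_rf(fit, bench_pp(), units = 1, n_probes = 50,
                               seed = 3)
  expect_identical(dim(rf[[1]]), c(12L, 12L))
  for (i in 1:20) {
    img <- numeric(784)
    img[occrobust:::with_seed(occrobust:::substream_seed(3, i),
                              sample.int(784, 90))] <- 1
    expect_identical(sum(img != 0), 90L)
  }
})

test_that("reverse correlation recovers a linear unit's receptive field", {
  fit <- bench_fastica()
  pp <- bench_pp()
  units <- 1:4
  rfs <- reverse_correlation_rf(fit, pp, units, n_probes = 50000, seed = 11)
  # the estimate is the true map filtered by the probe-ensemble covariance,
  # so recovery is strong but not perfect; each map must in addition identify
  # its own unit against every other unit's weight map
  maps <- lapply(seq_len(16), function(u)
    as.vector(weight_image(fit$W[u, 1:144], fit$W[u, 145:288])))
  for (k in seq_along(units)) {
    cors <- abs(vapply(maps, function(m) cor(as.vector(rfs[[k]]), m),
                       numeric(1)))
    expect_gt(cors[units[k]], 0.75)
    expect_identical(which.max(cors), as.integer(units[k]))
  }
  # a dead unit maps to (numerically) nothing
  dead <- fit
  dead$W[1, ] <- 0
  rf0 <- reverse_correlation_rf(dead, pp, 1, n_probes = 200, seed = 12)
  expect_true(all(abs(rf0[[1]]) < 1e-12))
})

test_that("lateral selectivity is zero and stable without lateral weights", {
  fit <- bench_hnn()
  off <- ablate(fit)
  ls <- lateral_selectivity(off, n_neurons = 5, top_k = 10, seed = 4)
  expect_equal(ls$statistic, 0, tolerance = 1e-12)
  # ties broken by unit index: ranked targets are simply in index order
  expect_identical(ls$targets[[1]], setdiff(seq_len(fit$n_units),
                                            ls$neurons[1]))
})

test_that("the selectivity statistic is invariant under unit relabeling", {
  set.seed(86)
  n <- 25
  C <- matrix(runif(n * n, 0.01, 1), n, n); diag(C) <- 0
  Wff <- matrix(rnorm(n * 288), n, 288)
  st <- structure(list(Wff = Wff, C = C, n_units = n),
                  class = c("hnn", "coding_model"))
  perm <- rev(seq_len(n))
  st2 <- st
  st2$C <- C[perm, perm]
  st2$Wff <- Wff[perm, ]
  ls1 <- lateral_selectivity(st, n_neurons = n, top_k = 5, seed = 4)
  ls2 <- lateral_selectivity(st2, n_neurons = n, top_k = 5, seed = 4)
  expect_equal(sort(ls1$per_neuron), sort(ls2$per_neuron), tolerance = 1e-12)
})
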