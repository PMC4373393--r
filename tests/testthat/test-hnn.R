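toy_hnn <- function(Wff, C, steps = 400) {
  n <- nrow(Wff)
  structure(list(Wff = Wff, C = C, theta = rep(1, n), xbar = rep(0, ncol(Wff)),
                 cabar = rep(0, n), tau_r = 10, tau_ca = 2, eta_ff = 2e-3,
                 eta_lat = 3e-3, eta_theta = 0.01, p = 0.1, steps = steps,
                 mean_rate = 0.01, n_units = n, ablated = FALSE),
            class = c("hnn", "coding_model"))
}

test_that("settled rates match the analytic threshold-linear fixed point", {
  st <- toy_hnn(diag(2), matrix(c(0, 0.3, 0.3, 0), 2, 2))
  x <- c(1, 0.8)
  r <- hnn_settle(x, st)$r
  expect_equal(as.vector(r), as.vector(solve(diag(2) + st$C, st$Wff %*% x)),
               tolerance = 1e-8)
  # zero input: rates stay at zero throughout
  expect_true(all(hnn_settle(c(0, 0), st)$r == 0))
  # no inhibition: rates converge to the rectified feedforward drive
  st0 <- toy_hnn(matrix(c(1, -1, 0.5, 0.2), 2, 2), matrix(0, 2, 2))
  x <- c(1, 0.5)
  expect_equal(as.vector(hnn_settle(x, st0)$r),
               as.vector(pmax(st0$Wff %*% x, 0)), tolerance = 1e-8)
})

test_that("rates are non-negative at every integration step", {
  set.seed(71)
  st <- toy_hnn(matrix(rnorm(4 * 288), 4), 2 - diag(2, 4))
  x <- abs(rnorm(288))
  for (k in c(1, 2, 5, 20, 100)) {
    out <- hnn_settle(x, st, steps = k)
    expect_true(all(out$r >= 0))
  }
})

test_that("learning is silent at steady zero activity", {
  st <- toy_hnn(diag(2), matrix(0, 2, 2))
  st$xbar <- c(0.5, 0.5)
  up <- hnn_learn_step(st, x = c(0.5, 0.5), ca = c(0, 0))
  expect_equal(up$Wff, st$Wff)
  expect_equal(up$C, st$C)
})

test_that("coactivity grows lateral weights; silence between units decays them", {
  st <- toy_hnn(diag(3), matrix(0.05, 3, 3) - diag(0.05, 3))
  for (i in 1:3000) st <- hnn_learn_step(st, x = c(1, 1, 0), ca = c(1, 1, 0))
  expect_gt(st$C[1, 2], 0.05)      # coactive pair: inhibition grows
  expect_identical(st$C[1, 3], 0)  # never-coactive pair: decays, clipped at 0
  expect_true(all(diag(st$C) == 0) && all(st$C >= 0))
})

test_that("the Oja decay keeps feedforward norms bounded", {
  set.seed(72)
  st <- toy_hnn(matrix(runif(2 * 20, 0, 0.3), 2, 20), matrix(0, 2, 2))
  norms <- numeric(200)
  for (i in 1:10000) {
    x <- abs(rnorm(20))
    ca <- as.vector(pmax(st$Wff %*% x, 0))
    st <- hnn_learn_step(st, x, ca)
    if (i %% 50 == 0) norms[i / 50] <- sqrt(sum(st$Wff[1, ]^2))
  }
  expect_true(all(is.finite(st$Wff)))
  expect_lt(max(norms), 20)                # no divergence over 10,000 steps
  expect_lt(diff(range(norms[150:200])), 0.5 * max(norms))  # settles
})

test_that("training is deterministic and the state well-formed", {
  X <- tiny_inputs()$X[, 1:100]
  f1 <- hnn(X, 8, n_presentations = 300, seed = 12)
  f2 <- hnn(X, 8, n_presentations = 300, seed = 12)
  expect_identical(f1$Wff, f2$Wff)
  expect_identical(f1$C, f2$C)
  expect_true(all(f1$C >= 0) && all(diag(f1$C) == 0))
})

test_that("the trained network has digit-like weights and selective inhibition", {
  fit <- bench_hnn()
  cc <- class_template_correlation(fit, bench_train_inputs())
  expect_gte(mean(cc > 0.5, na.rm = TRUE), 0.7)
  ls <- lateral_selectivity(fit, n_neurons = 10, top_k = 10, seed = 5)
  expect_gt(ls$statistic, 0)
})

test_that("ablation removes inhibition and densifies the code", {
  fit <- bench_hnn()
  ab <- ablate(fit)
  expect_true(all(ab$C == 0))
  X <- bench_train_inputs()$X[, 1:500]
  # without inhibition the settled rates are the rectified feedforward drive
  # (to within the Euler settling precision, (1 - 1/tau_r)^steps ~ 3e-5)
  expect_equal(predict(ab, X), pmax(fit$Wff %*% X, 0), tolerance = 1e-3)
  s_int <- mean(col_sparseness(predict(fit, X)), na.rm = TRUE)
  s_abl <- mean(col_sparseness(predict(ab, X)), na.rm = TRUE)
  expect_lt(s_abl, s_int)
})

test_that("competition reduces coactivity of the population code", {
  fit <- bench_hnn()
  X <- bench_train_inputs()$X[, 1:300]
  mean_offdiag_cor <- function(Y) {
    keep <- apply(Y, 1, stats::sd) > 0
    cc <- stats::cor(t(Y[keep, ]))
    mean(cc[upper.tri(cc)])
  }
  expect_lt(mean_offdiag_cor(predict(fit, X)),
            mean_offdiag_cor(predict(ablate(fit), X)))
})
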