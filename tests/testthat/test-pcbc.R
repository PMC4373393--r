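toy_pcbc <- function(W, n_iter = 200) {
  structure(list(W = W / rowSums(W), V = W / apply(W, 1, max), beta = 0.01,
                 eps1 = 1e-6, eps2 = 1e-3, n_iter = n_iter,
                 n_units = nrow(W), ablated = FALSE),
            class = c("pcbc", "coding_model"))
}

test_that("error units divide input by reconstruction", {
  V <- diag(3)
  expect_equal(as.vector(pcbc_error(c(0, 0, 0), V, c(1, 1, 1))), c(0, 0, 0))
  # reconstruction equal to input, eps1 negligible: error is unity
  y <- c(2, 0.5, 1)
  x <- crossprod(V, y)
  expect_equal(as.vector(pcbc_error(x, V, y)), rep(1, 3), tolerance = 1e-5)
  # y = 0: error is x / eps1, by hand on a 3-dim example
  x <- c(0.3, 0, 1.2)
  expect_equal(as.vector(pcbc_error(x, V, c(0, 0, 0), eps1 = 1e-6)),
               c(0.3e6, 0, 1.2e6))
})

test_that("settling finds the matching unit on orthogonal patterns", {
  st <- toy_pcbc(diag(3))
  s <- pcbc_settle(c(1, 0, 0), st)
  expect_equal(which.max(s$y), 1L)
  expect_lt(max(s$y[-1]) / s$y[1], 0.01)
  expect_true(all(s$y >= 0))
  # multiplicative fixed point: W e = 1 on the active unit
  expect_equal(as.vector(st$W %*% s$e)[1], 1, tolerance = 1e-2)
  # zero input leaves all activity at the floor scale
  s0 <- pcbc_settle(c(0, 0, 0), st)
  expect_true(all(s0$y < 10 * st$eps2))
})

test_that("perfect reconstruction or silence leaves weights unchanged", {
  set.seed(61)
  W <- matrix(runif(12), 3, 4)
  st <- toy_pcbc(W)
  up <- pcbc_learn_step(st, y = c(0.5, 0.2, 0), e = rep(1, 4))
  expect_equal(up$W, st$W)
  up2 <- pcbc_learn_step(st, y = c(0, 0, 0), e = c(2, 0.5, 1, 3))
  expect_equal(up2$W, st$W)
})

test_that("under-reconstructed inputs strengthen the active unit's weights", {
  W <- matrix(c(0.6, 0.4, 0.3, 0.7), 2, 2, byrow = TRUE)
  st <- toy_pcbc(W)
  e <- c(2, 1)   # first input under-reconstructed
  pre <- st$W * (1 + st$beta * outer(c(1, 0), e - 1))
  expect_gt(pre[1, 1], st$W[1, 1])     # active unit, e > 1: grows
  expect_equal(pre[1, 2], st$W[1, 2])  # e = 1: unchanged
  expect_equal(pre[2, ], st$W[2, ])    # silent unit: unchanged
})

test_that("training is deterministic and inert at beta = 0", {
  X <- tiny_inputs()$X[, 1:100]
  f0 <- pcbc(X, 8, n_presentations = 50, beta = 0, n_iter_train = 5,
             seed = 9)
  finit <- with(list(), {  # same seed, zero presentations: the raw init
    pcbc(X, 8, n_presentations = 1, beta = 0, n_iter_train = 1, seed = 9)
  })
  expect_equal(f0$W, finit$W)
  f1 <- pcbc(X, 8, n_presentations = 200, n_iter_train = 5, seed = 10)
  f2 <- pcbc(X, 8, n_presentations = 200, n_iter_train = 5, seed = 10)
  expect_identical(f1$W, f2$W)
  expect_true(all(f1$W >= 0) && all(f1$V >= 0))
})

test_that("the trained network develops distributed digit-like weights", {
  fit <- bench_pcbc()
  cc <- class_template_correlation(fit, bench_train_inputs())
  expect_gte(mean(cc > 0.5, na.rm = TRUE), 0.8)
  # codes are spread over many units, not collapsed onto one winner
  Y <- predict(fit, bench_train_inputs()$X[, 1:500])
  expect_gt(length(unique(apply(Y, 2, which.max))), 32)
})

test_that("ablation = single-iteration encoding, with a denser code", {
  fit <- bench_pcbc()
  ab <- ablate(fit)
  X <- bench_train_inputs()$X[, 1:500]
  expect_identical(predict(ab, X), pcbc_settle(X, fit, n_iter = 1)$y)
  s_full <- mean(col_sparseness(predict(fit, X)), na.rm = TRUE)
  s_abl <- mean(col_sparseness(predict(ab, X)), na.rm = TRUE)
  expect_lt(s_abl, s_full)
  expect_true(all(colSums(predict(ab, X)) > 0) &&
                all(colSums(predict(fit, X)) > 0))
})

test_that("settling reduces the reconstruction error versus one iteration", {
  fit <- bench_pcbc()
  X <- bench_train_inputs()$X[, 1:200]
  Y200 <- predict(fit, X)
  Y1 <- pcbc_settle(X, fit, n_iter = 1)$y
  err <- function(Y) colSums(abs(X - crossprod(fit$V, Y)))
  expect_gte(mean(err(Y200) < err(Y1)), 0.95)
})
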