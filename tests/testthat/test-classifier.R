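# Penalized single-hidden-layer classifier.

test_that("the forward pass matches hand-computed probabilities", {
  m0 <- nn_model(rep(0, ersplearn:::n_weights(2, 3)), M = 2, p = 3, lambda = 0)
  pr <- nn_forward(m0, matrix(rnorm(12), 4))
  expect_true(all(abs(pr$f_nogo - 0.5) < 1e-12))
  # 1 feature, M = 1, alpha = (0, 1), beta = (0, 2), x = 0:
  # z = logistic(0) = 0.5, f_NoGo = logistic(2 * 0.5) = 0.7310586
  m1 <- nn_model(c(0, 1, 0, 2), M = 1, p = 1, lambda = 0)
  expect_equal(nn_forward(m1, 0)$f_nogo, 1 / (1 + exp(-1)), tolerance = 1e-12)
  # output saturates as beta grows with z fixed
  mbig <- nn_model(c(0, 1, 0, 500), M = 1, p = 1, lambda = 0)
  expect_gt(nn_forward(mbig, 0)$f_nogo, 1 - 1e-12)
  expect_error(nn_forward(m1, c(1, 2)), class = "ersplearn_dim_mismatch")
})

test_that("the loss decomposes exactly and excludes biases from the penalty", {
  set.seed(5)
  M <- 3; p <- 4; n <- 8
  X <- matrix(rnorm(n * p), n)
  y <- rbinom(n, 1, 0.5)
  th <- runif(ersplearn:::n_weights(M, p), -0.5, 0.5)
  lv <- nn_loss(th, X, y, M, lambda = 0.01)
  expect_equal(lv$total, lv$ce + 0.01 * lv$penalty, tolerance = 1e-12)
  w <- ersplearn:::unpack_theta(th, M, p)
  expect_equal(lv$penalty, sum(w$alpha[, -1]^2) + sum(w$beta[-1]^2),
               tolerance = 1e-12)
  lvb <- nn_loss(th, X, y, M, lambda = 0.01, penalize_bias = TRUE)
  expect_equal(lvb$penalty, sum(w$alpha^2) + sum(w$beta^2), tolerance = 1e-12)
  # all-zero weights: cross-entropy is exactly n log 2
  lv0 <- nn_loss(rep(0, length(th)), X, y, M, lambda = 0.01)
  expect_equal(lv0$ce, n * log(2), tolerance = 1e-12)
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(6)
  M <- 3; p <- 5; n <- 7
  X <- matrix(rnorm(n * p), n)
  y <- rbinom(n, 1, 0.5)
  for (rep in 1:10) {
    th <- runif(ersplearn:::n_weights(M, p), -1, 1)
    g <- nn_grad(th, X, y, M, 0.01)
    gn <- vapply(seq_along(th), function(i) {
      h <- 1e-6
      tp <- th; tp[i] <- tp[i] + h
      tm <- th; tm[i] <- tm[i] - h
      (nn_loss(tp, X, y, M, 0.01)$total - nn_loss(tm, X, y, M, 0.01)$total) /
        (2 * h)
    }, 0)
    expect_lt(max(abs(g - gn)) / max(1, max(abs(gn))), 1e-6)
  }
})

test_that("training separates a separable toy set and respects the penalty limit", {
  set.seed(7)
  X <- rbind(matrix(rnorm(40, -2), 20, 2), matrix(rnorm(40, 2), 20, 2))
  y <- factor(rep(c("Go", "NoGo"), each = 20), levels = c("Go", "NoGo"))
  m <- nn_train(X, y, M = 4, lambda = 0.005, seed = 1)
  expect_equal(mean(nn_forward(m, X)$chat == y), 1)
  # huge penalty shrinks weights toward zero; predictions go to prevalence
  mbig <- nn_train(X, y, M = 4, lambda = 1e3, seed = 1)
  expect_lt(sum(mbig$alpha[, -1]^2) + sum(mbig$beta[-1]^2), 1e-3)
  expect_true(all(abs(nn_forward(mbig, X)$f_nogo - 0.5) < 0.05))
  # determinism and the restart contract
  m2 <- nn_train(X, y, M = 4, lambda = 0.005, seed = 1)
  expect_identical(m$theta, m2$theta)
  expect_lte(m$meta$loss, m$meta$init_loss)
})

test_that("swapping class labels mirrors the fitted probabilities", {
  set.seed(8)
  X <- rbind(matrix(rnorm(60, -1.5), 30, 2), matrix(rnorm(60, 1.5), 30, 2))
  y <- factor(rep(c("Go", "NoGo"), each = 30), levels = c("Go", "NoGo"))
  ys <- factor(ifelse(y == "Go", "NoGo", "Go"), levels = c("Go", "NoGo"))
  m1 <- nn_train(X, y, M = 2, lambda = 0.01, seed = 2, restarts = 5)
  m2 <- nn_train(X, ys, M = 2, lambda = 0.01, seed = 2, restarts = 5)
  expect_equal(nn_forward(m2, X)$f_nogo, nn_forward(m1, X)$f_go,
               tolerance = 1e-3)
})

test_that("the optimal penalty norm is non-increasing in lambda", {
  set.seed(9)
  X <- rbind(matrix(rnorm(40, -1), 20, 2), matrix(rnorm(40, 1), 20, 2))
  y <- factor(rep(c("Go", "NoGo"), each = 20), levels = c("Go", "NoGo"))
  norms <- vapply(c(1e-4, 1e-3, 1e-2, 1e-1, 1), function(lam) {
    m <- nn_train(X, y, M = 2, lambda = lam, seed = 3, restarts = 10)
    sum(m$alpha[, -1]^2) + sum(m$beta[-1]^2)
  }, 0)
  expect_true(all(diff(norms) <= 1e-6 + 0.02 * norms[-length(norms)]))
})

test_that("the fit matches an established weight-decay implementation", {
  skip_if_not_installed("nnet")
  set.seed(10)
  X <- rbind(matrix(rnorm(60, -1), 30, 2), matrix(rnorm(60, 1), 30, 2))
  y01 <- rep(c(0, 1), each = 30)
  M <- 3; lam <- 0.01
  nf <- nnet::nnet(X, y01, size = M, decay = lam, entropy = TRUE,
                   maxit = 500, trace = FALSE)
  # repack nnet weights into this package's layout and evaluate both fits
  # under the same penalized loss (nnet's decay penalizes biases too)
  w <- nf$wts
  alpha <- t(matrix(w[seq_len(M * 3)], 3, M))          # unit-wise (b, w1, w2)
  beta <- w[M * 3 + seq_len(M + 1)]
  th_nnet <- c(as.numeric(alpha), beta)
  loss_nnet <- nn_loss(th_nnet, X, y01, M, lam, penalize_bias = TRUE)$total
  # identical loss formula: this package's penalized loss evaluated at
  # nnet's weights equals nnet's own objective value
  expect_equal(loss_nnet, nf$value, tolerance = 1e-6)
  # and with enough restarts the optimizer reaches at least as good a fit
  mine <- nn_train(X, y01, M = M, lambda = lam, seed = 4, restarts = 20,
                   penalize_bias = TRUE)
  expect_lte(mine$meta$loss, loss_nnet * 1.02)
})
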