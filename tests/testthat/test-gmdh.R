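test_that("fit_neuron recovers exact polynomial relationships", {
  set.seed(51)
  x1 <- rnorm(20); x2 <- rnorm(20)
  lin <- fit_neuron(x1, x2, 1 + 2 * x1 + 3 * x2, fit_idx = 1:12)
  expect_equal(lin$w, c(1, 2, 3, 0), tolerance = 1e-8)
  expect_lt(lin$delta, 1e-10)
  inter <- fit_neuron(x1, x2, x1 * x2, fit_idx = 1:12)
  expect_equal(inter$w, c(0, 0, 0, 1), tolerance = 1e-8)
  expect_lt(inter$delta, 1e-10)
})

test_that("collinear inputs mark the neuron unfit", {
  set.seed(52)
  x <- rnorm(20)
  expect_warning(out <- fit_neuron(x, x, rnorm(20), fit_idx = 1:12),
                 "unfit")
  expect_true(out$unfit)
  expect_identical(out$delta, Inf)
  expect_error(fit_neuron(x, x, rnorm(20), fit_idx = 1:4), "at least 5")
})

test_that("fit_neuron matches the normal-equations oracle", {
  set.seed(53)
  for (i in 1:100) {
    n <- sample(10:50, 1)
    x1 <- rnorm(n); x2 <- rnorm(n); y <- rnorm(n)
    fi <- sort(sample(n, max(6, floor(0.7 * n))))
    got <- fit_neuron(x1, x2, y, fit_idx = fi)
    ora <- neuron_oracle(x1, x2, y, fi)
    expect_equal(got$w, ora$w, tolerance = 1e-8)
    expect_equal(got$delta, ora$delta, tolerance = 1e-8)
  }
})

test_that("selection keeps the lowest-error uncorrelated neurons", {
  sel <- bonetex:::select_best
  set.seed(54)
  yh <- matrix(rnorm(24), 8, 3)
  expect_identical(sel(c(0.5, 0.2, 0.9), yh, F = 2, rho_max = 0.999),
                   c(2L, 1L))
  # duplicated outputs: only one survives
  yh2 <- cbind(yh[, 1], yh[, 1])
  expect_identical(sel(c(0.3, 0.2), yh2, F = 2, rho_max = 0.999), 2L)
  # iid outputs, F = 5 of 10: exactly 5 kept
  yh3 <- matrix(rnorm(80), 8, 10)
  expect_length(sel(runif(10), yh3, F = 5, rho_max = 0.999), 5L)
  # degenerate limit: rho_max = 1 and F = K keeps every fit neuron
  expect_length(sel(runif(10), yh3, F = 10, rho_max = 1), 10L)
  # unfit neurons (Inf delta) are never selected
  expect_identical(sel(c(Inf, 0.1), yh2, F = 2, rho_max = 0.999), 2L)
})

test_that("layer bookkeeping follows the pairwise-combination formula", {
  set.seed(55)
  X <- matrix(rnorm(40 * 14), 40, 14)
  y <- rep(c(0, 1), 20)
  net <- gmdh_train(X, y, gmdh_config(max_layers = 3), seed = 2)
  l1 <- net$layers[[1]]
  expect_equal(l1$m_r, 14L)
  expect_equal(l1$K_r, 14 * 13 / 2)
  for (l in net$layers) {
    expect_equal(l$K_r, l$m_r * (l$m_r - 1) / 2)
    expect_lte(l$F_r, 14)  # freedom of choice F = m by default
    if (l$r > 1) expect_equal(l$m_r, net$layers[[l$r - 1]]$F_r + 14L)
    expect_true(all(diff(l$delta) >= 0))
  }
})

test_that("an exactly representable target is learned to zero error", {
  set.seed(56)
  fx <- and_fixture(n = 40)
  net <- gmdh_train(fx$X, fx$y, gmdh_config(max_layers = 3), seed = 3)
  pr <- predict(net, fx$X)
  expect_equal(mean(pr$label == fx$y), 1)
  expect_equal(pr$score, fx$y, tolerance = 1e-6)
  expect_lt(net$output_delta, 1e-8)
})

test_that("pure-noise targets stop growth without crashing", {
  set.seed(57)
  X <- matrix(rnorm(40 * 10), 40, 10)
  y <- rep(c(0, 1), 20)
  net <- gmdh_train(X, y, seed = 4)
  expect_s3_class(net, "gmdh_network")
  expect_lte(length(net$layers), net$config$max_layers)
  acc <- mean(predict(net, X)$label == y)
  expect_gte(acc, 0)  # reported, whatever it is
})

test_that("training is exactly reproducible given the seed", {
  set.seed(58)
  X <- matrix(rnorm(30 * 6), 30, 6)
  y <- rep(c(0, 1), 15)
  n1 <- gmdh_train(X, y, seed = 9)
  n2 <- gmdh_train(X, y, seed = 9)
  expect_equal(n1$layers, n2$layers)
  expect_identical(predict(n1, X), predict(n2, X))
})

test_that("degenerate inputs are refused", {
  X <- matrix(rnorm(40), 20, 2)
  expect_error(gmdh_train(X, rep(1, 20), seed = 1), "one class")
  expect_error(gmdh_train(X, rep(c(0, 2), 10), seed = 1), "0/1")
  expect_error(gmdh_train(X[1:5, ], rep(c(0, 1), 5)[1:5], seed = 1),
               "at least 10")
  expect_error(gmdh_train(X[, 1, drop = FALSE], rep(c(0, 1), 10),
                          seed = 1), "at least 2")
})

test_that("prediction validates the feature count and is functional", {
  set.seed(59)
  fx <- and_fixture(n = 30)
  net <- gmdh_train(fx$X, fx$y, seed = 5)
  expect_error(predict(net, fx$X[, 1, drop = FALSE]), "columns")
  # output neuron built on features 1 and 2 ignores added constants
  p1 <- predict(net, fx$X)
  p2 <- predict(net, fx$X)
  expect_identical(p1, p2)
})

test_that("feature importance traces the output neuron's ancestry", {
  set.seed(60)
  # noise features 3..5 never help the exactly-representable target
  fx <- and_fixture(n = 40, m = 2)
  X <- cbind(fx$X, matrix(rnorm(40 * 3), 40, 3))
  net <- gmdh_train(X, fx$y, seed = 6)
  imp <- gmdh_importance(net)
  expect_length(imp, 5L)
  expect_equal(sum(imp), 1)
  expect_equal(sum(imp[1:2]), 1)  # all mass on the two true features
  # features outside the output neuron's ancestry cannot move the score
  X2 <- X; X2[, 4] <- X2[, 4] + 100
  expect_equal(predict(net, X2)$score, predict(net, X)$score)
  # a single-layer two-feature net splits importance evenly
  net2 <- gmdh_train(fx$X, fx$y, gmdh_config(max_layers = 1), seed = 7)
  expect_equal(unname(gmdh_importance(net2)), c(0.5, 0.5))
})
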