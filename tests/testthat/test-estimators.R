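test_that("fractional errors behave as received/predicted - 1", {
  b <- random_basis(3, 6, w0 = 1, seed = 21)
  x <- c(0.5, 1, 0)
  mu <- mean_input(b, x)
  expect_equal(fractional_errors(b, x, mu), rep(0, 6))       # perfect prediction
  expect_equal(fractional_errors(b, x, 2 * mu), rep(1, 6))   # doubled input
  expect_equal(fractional_errors(b, x, rep(0, 6)), rep(-1, 6)) # floor
})

test_that("poisson_loglik gradient matches the weighted fractional errors", {
  b <- random_basis(4, 8, w0 = 1.5, seed = 22)
  set.seed(23)
  x <- runif(4, 0.2, 2)
  s <- sample_inputs(b, x, seed = 24)
  analytic <- drop(crossprod(b$weights, fractional_errors(b, x, s)))
  h <- 1e-6
  numeric <- vapply(1:4, function(i) {
    e <- numeric(4); e[i] <- h
    (poisson_loglik(b, x + e, s) - poisson_loglik(b, x - e, s)) / (2 * h)
  }, 0)
  expect_equal(numeric, analytic, tolerance = 1e-5)
})

test_that("a perfectly predicted input is a fixed point of both steps", {
  b <- random_basis(3, 5, w0 = 1, seed = 25)
  x <- c(1, 0.3, 2)
  s <- mean_input(b, x)
  st <- list(x_hat = x, iter = 0L)
  expect_equal(divisive_step(b, st, s)$x_hat, x, tolerance = 1e-12)
  expect_equal(subtractive_step(b, st, s)$x_hat, x, tolerance = 1e-12)
})

test_that("symmetric one-feature case converges to the shared mean", {
  b <- build_basis("paired", n_features = 1, m_inputs = 2, background = 1)
  # analytically w*x + w0 = mean(s) => x = 99/40 = 2.475, for both models
  fit_d <- run_to_convergence(b, c(100, 100), estimator_config(tol = 1e-10))
  expect_true(fit_d$converged)
  expect_equal(coef(fit_d), 2.475, tolerance = 1e-6)
  fit_s <- run_to_convergence(b, c(100, 100), estimator_config(tol = 1e-10),
                              mode = "subtractive")
  expect_equal(coef(fit_s), 2.475, tolerance = 1e-6)
})

test_that("noiseless inputs recover the generating features exactly", {
  b <- random_basis(4, 9, w0 = 1, seed = 26)
  x_true <- c(1.2, 0.4, 2, 0.8)
  s <- mean_input(b, x_true)
  x_ml <- divisive_ml(b, s, tol = 1e-13)
  expect_equal(as.numeric(x_ml), x_true, tolerance = 1e-6)
  # the likelihood oracle agrees that x_true is the maximizer
  expect_gte(poisson_loglik(b, x_true, s),
             poisson_loglik(b, x_true * 1.01, s))
  expect_equal(as.numeric(subtractive_closed_form(b, s)), x_true,
               tolerance = 1e-9)
})

test_that("divisive fixed point matches the grid-search ML oracle", {
  for (seed in 31:35) {
    set.seed(seed)
    n <- sample(1:3, 1)
    m <- sample(4:10, 1)
    b <- random_basis(n, m, w0 = 1, seed = seed)
    x_true <- runif(n, 0.5, 3)
    s <- sample_inputs(b, x_true, seed = seed + 100)
    x_hat <- as.numeric(divisive_ml(b, s, tol = 1e-13))
    x_grid <- grid_search_ml(b, s)
    expect_equal(x_hat, x_grid,
                 tolerance = 1e-3 * max(1, max(x_grid)))
  }
})

test_that("all three divisive solvers agree on generic instances", {
  b <- random_basis(3, 8, w0 = 1, seed = 41)
  set.seed(42)
  s <- sample_inputs(b, c(1, 2, 0.5), seed = 43)
  x_dyn <- coef(run_to_convergence(b, s, estimator_config(tol = 1e-11)))
  x_ml <- as.numeric(divisive_ml(b, s, tol = 1e-13))
  x_front <- coef(feature_estimate(b, s))
  expect_equal(x_dyn, x_ml, tolerance = 1e-3)
  expect_equal(x_front, x_ml, tolerance = 1e-6)
})

test_that("likelihood ascends along divisive iterates", {
  for (seed in 51:60) {
    b <- random_basis(3, 6, w0 = 1, seed = seed)
    set.seed(seed)
    s <- sample_inputs(b, runif(3, 0, 2), seed = seed + 1)
    cfg <- estimator_config(max_iters = 400L)
    st <- list(x_hat = numeric(3), iter = 0L)
    ll_prev <- poisson_loglik(b, st$x_hat, s)
    for (i in 1:400) {
      st <- divisive_step(b, st, s, cfg)
      ll <- poisson_loglik(b, st$x_hat, s)
      expect_gte(ll, ll_prev - 1e-8)
      ll_prev <- ll
    }
  }
})

test_that("inputs below the background drive the estimate to zero", {
  b <- random_basis(3, 6, w0 = 5, seed = 61)
  s <- rep(1, 6)   # all inputs below w0: every gradient negative at 0
  fit <- run_to_convergence(b, s, estimator_config(tol = 1e-10))
  expect_true(fit$converged)
  expect_equal(coef(fit), rep(0, 3))
  expect_equal(as.numeric(divisive_ml(b, s, tol = 1e-12)), rep(0, 3),
               tolerance = 1e-6)
})

test_that("subtractive dynamics reach the closed form unclamped", {
  b <- random_basis(3, 7, w0 = 1, seed = 62)
  set.seed(63)
  s <- sample_inputs(b, c(2, 1, 1.5), seed = 64)
  cf <- attr(subtractive_closed_form(b, s), "unclamped")
  fit <- run_to_convergence(
    b, s, estimator_config(tol = 1e-13, clamp_nonnegative = FALSE,
                           max_iters = 2e5L),
    mode = "subtractive")
  expect_equal(coef(fit), cf, tolerance = 1e-8)
  # and the clamped projected-gradient solver agrees when cf is interior
  expect_true(all(cf > 0))
  expect_equal(as.numeric(subtractive_nnls(b, s, tol = 1e-13)), cf,
               tolerance = 1e-8)
})

test_that("closed form reduces to per-feature projection for orthogonal W", {
  W <- matrix(0, 6, 3)
  W[1:2, 1] <- c(3, 4); W[3:4, 2] <- c(1, 2); W[5:6, 3] <- c(5, 1)
  b <- feature_basis(W, 1)
  s <- c(10, 3, 4, 9, 2, 8)
  by_proj <- vapply(1:3, function(i) {
    w <- W[, i]
    sum(w * (s - 1)) / sum(w^2)
  }, 0)
  expect_equal(attr(subtractive_closed_form(b, s), "unclamped"), by_proj,
               tolerance = 1e-12)
})

test_that("singular normal equations error and suggest ridge", {
  W <- cbind(c(1, 1), c(1, 1))
  b <- feature_basis(W, 1)
  expect_error(subtractive_closed_form(b, c(5, 5)), "ridge")
  expect_silent(subtractive_closed_form(b, c(5, 5), ridge = 1e-6))
})

test_that("scaling the input scales the interior divisive fixed point", {
  b <- random_basis(3, 8, w0 = 1e-8, seed = 65)  # negligible background
  set.seed(66)
  x_true <- runif(3, 1, 3)
  s <- mean_input(b, x_true)
  x1 <- as.numeric(divisive_ml(b, s, tol = 1e-13))
  x3 <- as.numeric(divisive_ml(b, 3 * s, tol = 1e-13))
  expect_equal(x3, 3 * x1, tolerance = 1e-5)
})

test_that("averaging over Poisson trials shrinks the estimation bias", {
  b <- random_basis(2, 6, w0 = 1, seed = 67)
  x_true <- c(1.5, 0.7)
  err <- vapply(c(20L, 500L), function(tr) {
    s_bar <- rowMeans(sample_inputs(b, x_true, trials = tr, seed = 68))
    max(abs(as.numeric(divisive_ml(b, s_bar, tol = 1e-12)) - x_true))
  }, 0)
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.05)
})

test_that("effective weights shrink under population activity", {
  b <- random_basis(4, 6, w0 = 2, seed = 69)
  expect_equal(effective_weights(b, rep(0, 4)), b$weights / 2)
  set.seed(70)
  r <- runif(4, 0.5, 2)
  ew1 <- effective_weights(b, r)
  ew2 <- effective_weights(b, 2 * r)
  expect_true(all(ew2 <= ew1 + 1e-12))
  expect_true(all(ew1 <= b$weights / 2 + 1e-12))
  # doubling activity with negligible background roughly halves the weights
  b0 <- feature_basis(b$weights, 1e-9)
  expect_equal(effective_weights(b0, 2 * r),
               effective_weights(b0, r) / 2, tolerance = 1e-6)
})

test_that("divisive dynamics select a graded optimum on overlapping bases", {
  b <- build_basis("circular", n_features = 30, background = 0.01)
  s <- mean_input(b, replace(numeric(30), 15, 1))
  x_dyn <- as.numeric(divisive_dynamics(b, s, tol = 1e-7,
                                        max_iter = 30000L))
  x_sharp <- as.numeric(divisive_ml(b, s, tol = 1e-10, relax = 1.9))
  # near-identical likelihood (nearly flat optimal face), but very
  # different representatives: the dynamics keep many features active
  ll_dyn <- poisson_loglik(b, x_dyn, s)
  ll_sharp <- poisson_loglik(b, x_sharp, s)
  expect_lt(abs(ll_dyn - ll_sharp) / abs(ll_sharp), 0.01)
  expect_gt(sum(x_dyn > 0.01), sum(x_sharp > 0.01))
})

test_that("non-convergence is flagged, not thrown", {
  b <- random_basis(3, 6, w0 = 1, seed = 71)
  s <- sample_inputs(b, c(1, 1, 1), seed = 72)
  fit <- run_to_convergence(b, s, estimator_config(max_iters = 3L))
  expect_false(fit$converged)
  expect_equal(fit$iter, 3L)
})
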