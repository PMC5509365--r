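two_unit_params <- function(w0 = 1)
  network_params(feature_basis(matrix(c(40, 40), 2, 1), w0))

test_that("quiescent network stays quiescent", {
  p <- two_unit_params()
  st <- list(r_exc = c(0, 0), r_inh = 0, t = 0)
  st2 <- network_step(p, st, c(0, 0))
  expect_equal(st2$r_exc, c(0, 0))
  expect_equal(st2$r_inh, 0)
  tr <- simulate_network(p, c(0, 0), duration = 0.05)
  expect_equal(max(abs(tr$r_exc)), 0)
})

test_that("a network fixed point is invariant under one step", {
  p <- two_unit_params()
  s <- c(150, 50)
  # fixed point: r_exc = s / (w0 + w r_inh), sum of errors zero
  r_inh <- 2.475
  st <- list(r_exc = s / (1 + 40 * r_inh), r_inh = r_inh, t = 0)
  st2 <- network_step(p, st, s)
  expect_equal(st2$r_exc, st$r_exc, tolerance = 1e-9)
  expect_equal(st2$r_inh, st$r_inh, tolerance = 1e-9)
})

test_that("two-unit steady state matches the damped-iteration oracle", {
  p <- two_unit_params()
  s <- c(150, 50)
  tr <- simulate_network(p, s, duration = 60, stop_when_steady = TRUE,
                         steady_tol = 1e-7)
  fs <- final_state(tr)
  oracle <- two_unit_fixed_point(150, 50)
  expect_equal(fs$r_exc, oracle$r_exc, tolerance = 1e-4)
  expect_equal(fs$r_inh, oracle$r_inh, tolerance = 1e-4)
  # and the inhibitory unit carries the divisive estimate
  b <- p$basis
  expect_equal(fs$r_inh, as.numeric(divisive_ml(b, s, tol = 1e-12)),
               tolerance = 1e-3)
})

test_that("perfectly predicted input drives excitatory rates to one", {
  b <- build_basis("paired", n_features = 4, background = 1)
  p <- network_params(b)
  s <- mean_input(b, c(2, 1, 0.5, 1.5))
  tr <- simulate_network(p, s, duration = 60, stop_when_steady = TRUE,
                         steady_tol = 1e-7)
  expect_equal(final_state(tr)$r_exc, rep(1, 4), tolerance = 1e-3)
})

test_that("network steady state equals the divisive estimator generally", {
  for (seed in 81:83) {
    b <- anchored_basis(3, 6, w0 = 1, seed = seed)
    set.seed(seed)
    s <- sample_inputs(b, runif(3, 0.5, 2), seed = seed + 10)
    p <- network_params(b)
    tr <- simulate_network(p, s, duration = 80, stop_when_steady = TRUE,
                           steady_tol = 1e-6)
    x_hat <- as.numeric(divisive_ml(b, s, tol = 1e-12))
    expect_equal(final_state(tr)$r_inh, x_hat, tolerance = 1e-3)
  }
})

test_that("divisive steady excitatory rates are contrast invariant", {
  b <- feature_basis(matrix(c(40, 40), 2, 1), 1e-6)  # negligible floor
  p <- network_params(b)
  tr1 <- simulate_network(p, c(150, 50), duration = 60,
                          stop_when_steady = TRUE, steady_tol = 1e-7)
  tr3 <- simulate_network(p, 3 * c(150, 50), duration = 60,
                          stop_when_steady = TRUE, steady_tol = 1e-7)
  f1 <- final_state(tr1); f3 <- final_state(tr3)
  expect_equal(f3$r_exc, f1$r_exc, tolerance = 1e-3)
  expect_equal(f3$r_inh, 3 * f1$r_inh, tolerance = 1e-2)
})

test_that("closed forms agree with simulation up to one constant", {
  p <- two_unit_params()
  grid <- expand.grid(s1 = c(20, 60, 120), s2 = c(10, 80))
  ratio <- vapply(seq_len(nrow(grid)), function(i) {
    s <- c(grid$s1[i], grid$s2[i])
    fs <- final_state(simulate_network(p, s, duration = 60,
                                       stop_when_steady = TRUE,
                                       steady_tol = 1e-7))
    fs$r_exc[1] / steady_state_two_unit(s[1], s[2], 1)
  }, 0)
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-3)
  # formulas: arithmetic and limiting cases
  expect_equal(steady_state_two_unit(100, 100, 1), 0.5)
  expect_equal(steady_state_two_unit(0, 0, 1), 0)
  s1 <- c(0.001, 0.002)
  expect_equal(steady_state_two_unit(s1, 100, 1), s1 / (100 + s1),
               tolerance = 1e-9)
  # simple-stimulus form reduces to the two-unit form
  b <- feature_basis(matrix(c(40, 40), 2, 1), 1)
  expect_equal(steady_state_simple(b, c(70, 0))[1],
               steady_state_two_unit(70, 0, 1))
  # below the rectification floor responses are linear in s
  expect_equal(steady_state_simple(b, c(0.2, 0.3)), c(0.2, 0.3))
})

test_that("subtractive network settles on the least-squares estimate", {
  b <- random_basis(2, 4, w0 = 1, seed = 91)
  p <- network_params(b)
  set.seed(92)
  s <- sample_inputs(b, c(1.5, 0.8), seed = 93)
  tr <- simulate_network(p, s, duration = 60, mode = "subtractive",
                         stop_when_steady = TRUE, steady_tol = 1e-7)
  cf <- attr(subtractive_closed_form(b, s), "unclamped")
  expect_equal(final_state(tr)$r_inh, cf, tolerance = 1e-3)
  # from rest with zero input nothing moves
  tr0 <- simulate_network(p, rep(0, 4), duration = 0.05,
                          mode = "subtractive")
  expect_equal(max(abs(tr0$r_inh)), 0)
})

test_that("divisive excitatory transients overshoot their steady state", {
  p <- two_unit_params()
  tr <- simulate_network(p, c(100, 0), duration = 4, record_every = 2e-3)
  y <- tr$r_exc[, 1]
  expect_gt(max(y), 1.5 * y[length(y)])
})

test_that("time_to_fraction interpolates crossings", {
  ramp <- structure(list(times = seq(0, 1, by = 0.01),
                         r_exc = matrix(seq(0, 1, by = 0.01), ncol = 1),
                         r_inh = matrix(0, 101, 1)),
                    class = "ei_trace")
  expect_equal(time_to_fraction(ramp, 1, 0.5), 0.5, tolerance = 1e-9)
  expect_equal(time_to_fraction(ramp, 1, 1), 1)
  flat <- ramp; flat$r_exc[] <- 0
  expect_true(is.na(time_to_fraction(flat, 1, 0.5)))
})

test_that("time to peak shortens with input amplitude (divisive only)", {
  p <- two_unit_params()
  tp <- vapply(c(50, 100, 200), function(A) {
    tr <- simulate_network(p, c(A, 0), duration = 3, record_every = 2e-3)
    time_to_fraction(tr, 1, 1)
  }, 0)
  expect_true(all(diff(tp) < 0))
  tp_sub <- vapply(c(50, 100, 200), function(A) {
    tr <- simulate_network(p, c(A, 0), duration = 3, record_every = 2e-3,
                           mode = "subtractive")
    time_to_fraction(tr, 1, 1)
  }, 0)
  # linear dynamics: invariant up to the recording grid (2 ms)
  expect_lt(diff(range(tp_sub)) / mean(tp_sub), 0.01)
})

test_that("integration guards against instability and bad bookkeeping", {
  b <- feature_basis(matrix(c(40, 40), 2, 1), 1)
  p <- network_params(b, dt = 0.05)      # far beyond the stability bound
  expect_error(simulate_network(p, c(150, 50), duration = 1), "dt")
  p2 <- two_unit_params()
  tr <- simulate_network(p2, c(10, 10), duration = 0.01,
                         record_every = 0.01)
  expect_equal(length(tr$times), 2L)     # initial row plus one record
  df <- as.data.frame(tr)
  expect_named(df, c("time", "unit", "population", "rate"))
  expect_equal(nrow(df), 2 * 3)
})

test_that("piecewise-constant input segments are honoured", {
  p <- two_unit_params()
  inp <- list(times = c(0, 0.5), values = cbind(c(100, 0), c(0, 0)))
  tr <- simulate_network(p, inp, duration = 1, record_every = 0.01)
  on_idx <- tr$times > 0.05 & tr$times < 0.45
  off_idx <- tr$times > 0.95
  expect_gt(mean(tr$r_exc[on_idx, 1]), 1)
  expect_lt(tr$r_exc[sum(tr$times <= 1), 1][1], 0.5)
})

test_that("trace export writes the long table and manifest", {
  p <- two_unit_params()
  tr <- simulate_network(p, c(50, 10), duration = 0.02,
                         record_every = 0.01)
  f <- file.path(tempdir(), "trace_rt")
  write_trace(tr, f)
  tab <- read.delim(paste0(f, ".tsv"))
  expect_equal(sort(unique(tab$population)), c("exc", "inh"))
  man <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(man$a, 0.08)
  expect_equal(man$b, 40)
})
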