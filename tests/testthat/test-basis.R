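test_that("mean_input evaluates the generative model", {
  b <- build_basis("paired", n_features = 1, m_inputs = 2, background = 1)
  # zero stimulus leaves only the background
  expect_equal(mean_input(b, 0), c(1, 1))
  # hand arithmetic: 40 * 2.475 + 1 = 100 on both driven inputs
  expect_equal(mean_input(b, 2.475), c(100, 100))
  # floor at the background everywhere
  b2 <- random_basis(4, 7, w0 = 0.5, seed = 2)
  expect_true(all(mean_input(b2, runif(4)) >= 0.5))
  expect_error(mean_input(b2, c(1, 2)), "dimension")
})

test_that("mean_input is affine in the stimulus", {
  b <- random_basis(5, 9, w0 = 2, seed = 3)
  set.seed(4)
  for (rep in 1:5) {
    x1 <- runif(5); x2 <- runif(5)
    lhs <- mean_input(b, x1 + x2) - b$background
    rhs <- (mean_input(b, x1) - b$background) +
      (mean_input(b, x2) - b$background)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("Poisson sampling has unit Fano factor and seeded determinism", {
  b <- build_basis("paired", n_features = 3, background = 2)
  x <- c(0.5, 0, 1)
  draws <- sample_inputs(b, x, trials = 1e5, seed = 11)
  mu <- mean_input(b, x)
  fano <- apply(draws, 1, var) / rowMeans(draws)
  # var/mean ratio of a Poisson count is 1; s.e. of the ratio ~ sqrt(2/N)
  expect_true(all(abs(fano - 1) < 3 * sqrt(2 / 1e5)))
  expect_true(all(abs(rowMeans(draws) - mu) <
                    3 * sqrt(mu / 1e5)))
  expect_identical(sample_inputs(b, x, trials = 3, seed = 7),
                   sample_inputs(b, x, trials = 3, seed = 7))
  # baseline-only stimulus: every mean equals w0
  d0 <- sample_inputs(b, c(0, 0, 0), trials = 1e5, seed = 12)
  expect_true(all(abs(rowMeans(d0) - 2) < 3 * sqrt(2 / 1e5)))
})

test_that("gaussian sampling clips at zero and respects sigma", {
  b <- build_basis("paired", n_features = 2, background = 5)
  d <- sample_inputs(b, c(0, 0), noise = "gaussian", sigma = 1,
                     trials = 2e4, seed = 5)
  expect_true(all(d >= 0))
  expect_true(abs(sd(d[1, ]) - 1) < 0.05)
  expect_error(sample_inputs(b, c(0, 0), noise = "gaussian", sigma = -1))
})

test_that("paired basis drives two neighbouring inputs at full weight", {
  b <- build_basis("paired", n_features = 30, background = 1)
  for (i in c(1, 15, 30)) {
    col <- b$weights[, i]
    expect_equal(which(col > 0), sort(c(i, i %% 30 + 1)))
    expect_true(all(col[col > 0] == 40))
  }
})

test_that("circular basis is circulant with peak w_max", {
  b <- build_basis("circular", n_features = 30, background = 1)
  W <- b$weights
  expect_equal(diag(W), rep(40, 30))           # cosine term at its peak
  expect_equal(unname(colSums(W)), rep(sum(W[, 1]), 30))
  # columns are cyclic shifts of one another
  for (i in c(2, 17)) {
    shifted <- W[((seq_len(30) + i - 2) %% 30) + 1, i]
    expect_equal(shifted, W[, 1], tolerance = 1e-12)
  }
})

test_that("blob grid columns peak at the grid point nearest their centre", {
  b <- build_basis("blob_grid", n_features = 400, grid = c(30, 30),
                   background = 1)
  gx <- seq(0, 1, length.out = 30)
  xy <- cbind(rep(gx, each = 30), rep(gx, times = 30))
  for (i in c(1, 57, 400)) {
    d2 <- (xy[, 1] - b$centers[i, 1])^2 + (xy[, 2] - b$centers[i, 2])^2
    expect_equal(which.max(b$weights[, i]), which.min(d2))
  }
  # printed Gaussian value at an off-centre pixel
  i <- 57
  j <- 5
  expected <- 40 * exp(-((xy[j, 1] - b$centers[i, 1])^2 +
                           (xy[j, 2] - b$centers[i, 2])^2) / (2 * 0.1^2))
  expect_equal(b$weights[j, i], expected)
})

test_that("multiblob and letter bases have the declared structure", {
  b <- build_basis("multiblob", n_features = 8, grid = c(30, 30),
                   background = 1, seed = 9)
  expect_equal(dim(b$weights), c(900L, 8L))
  b2 <- build_basis("multiblob", n_features = 8, grid = c(30, 30),
                    background = 1, seed = 9)
  expect_identical(b$weights, b2$weights)     # seeded determinism
  lt <- build_basis("letters", background = 1)
  expect_equal(dim(lt$weights), c(600L, 3L))
  expect_identical(lt$feature_labels, c("V", "I", "A"))
  expect_true(all(lt$weights %in% c(0, 40)))
  # letters overlap pairwise (the point of the explaining-away demo)
  on <- lt$weights > 0
  expect_true(all(crossprod(on)[upper.tri(diag(3))] > 0))
})

test_that("basis serialization round-trips through text", {
  b <- build_basis("blob_grid", n_features = 16, grid = c(10, 10),
                   background = 0.5)
  f <- file.path(tempdir(), "basis_rt")
  write_basis(b, f)
  b2 <- read_basis(f)
  expect_equal(b2$weights, b$weights, tolerance = 1e-12)
  expect_equal(b2$background, b$background)
  expect_equal(b2$input_geometry, b$input_geometry)
})

test_that("invalid constructions are rejected", {
  expect_error(feature_basis(matrix(-1, 2, 2), 1), "nonnegative")
  expect_error(feature_basis(matrix(1, 2, 2), 0), "positive")
  expect_error(feature_basis(matrix(1, 4, 2), 1, input_geometry = c(3, 2)),
               "geometry")
  expect_error(build_basis("circular", n_features = 3, w_max = -1))
})
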