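# shared fixtures and independent oracles

# small random basis with well-separated (generic) columns
random_basis <- function(n, m, w0 = 1, seed = 1) {
  set.seed(seed)
  W <- matrix(stats::runif(m * n, 0.5, 40), m, n)
  feature_basis(W, w0)
}

# random basis in which each feature owns a strongly driven private
# receptor: keeps the likelihood well conditioned so that different
# algorithms agree on the coordinates of the optimum, not just its value
anchored_basis <- function(n, m, w0 = 1, seed = 1) {
  stopifnot(m >= n)
  set.seed(seed)
  W <- matrix(stats::runif(m * n, 0, 8), m, n)
  for (i in seq_len(n)) W[i, i] <- 40
  feature_basis(W, w0)
}

# brute-force maximizer of the Poisson log-likelihood on a refined grid;
# independent of the package's solvers (direct likelihood evaluation over
# an expanding/contracting lattice, n <= 3)
grid_search_ml <- function(basis, s, hi = NULL, levels = 6, pts = 13) {
  W <- basis$weights
  n <- ncol(W)
  stopifnot(n <= 3)
  hi <- hi %||% max((sum(s) + 1) / colSums(W)) * 1.5
  lo <- rep(0, n)
  up <- rep(hi, n)
  best <- rep(0, n)
  for (lev in seq_len(levels)) {
    axes <- lapply(seq_len(n), function(i)
      seq(lo[i], up[i], length.out = pts))
    grid <- as.matrix(do.call(expand.grid, axes))
    ll <- apply(grid, 1, function(x) poisson_loglik(basis, x, s))
    best <- grid[which.max(ll), ]
    span <- (up - lo) / (pts - 1)
    lo <- pmax(best - span, 0)
    up <- best + span
  }
  as.numeric(best)
}

# damped fixed-point iteration for the two-unit network steady state,
# independent of the Euler integrator
two_unit_fixed_point <- function(s1, s2, w = 40, w0 = 1, iters = 20000,
                                 damp = 0.05) {
  r <- 0
  for (i in seq_len(iters)) {
    e1 <- s1 / (w0 + w * r)
    e2 <- s2 / (w0 + w * r)
    g <- w * (e1 - 1) + w * (e2 - 1)
    r <- max(r + damp * g / (w * 2), 0)
  }
  e1 <- s1 / (w0 + w * r)
  e2 <- s2 / (w0 + w * r)
  list(r_exc = c(e1, e2), r_inh = r)
}
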