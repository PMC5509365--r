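#' Estimator configuration
#'
#' Controls the gradient dynamics that drive the feature estimate. The
#' update rate defaults to `1e-3 / max(colSums(W))`, small enough for smooth
#' ascent on every basis in the package; iteration stops when the largest
#' per-step change of the estimate falls below `tol`.
#'
#' @param eta update rate; `NULL` means the basis-dependent default above.
#' @param max_iters iteration cap.
#' @param tol convergence tolerance on `max(abs(dx))` per step.
#' @param clamp_nonnegative project the estimate onto `x >= 0` after each
#'   step (features are intensities; default `TRUE`).
#' @param loglik_every record the Poisson log-likelihood every this many
#'   iterations (the trace always includes the final value).
#' @return a list of class `estimator_config`.
#' @export
estimator_config <- function(eta = NULL, max_iters = 1e5L, tol = 1e-8,
                             clamp_nonnegative = TRUE, loglik_every = 50L) {
  if (!is.null(eta) && eta <= 0) stop("eta must be positive", call. = FALSE)
  if (max_iters < 1L) stop("max_iters must be >= 1", call. = FALSE)
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  structure(list(eta = eta, max_iters = as.integer(max_iters), tol = tol,
                 clamp_nonnegative = isTRUE(clamp_nonnegative),
                 loglik_every = as.integer(loglik_every)),
            class = "estimator_config")
}

default_eta <- function(basis) 1e-3 / max(colSums(basis$weights))

#' Fractional prediction errors
#'
#' The error signal that drives the divisive estimator: for each input,
#' the received activation divided by the activation predicted from the
#' current estimate, minus one: `s_j / (sum_k W[j,k] x_hat[k] + w0) - 1`.
#' It is zero when the input is perfectly predicted and can never fall
#' below -1.
#'
#' @param basis a [feature_basis()].
#' @param x_hat current feature estimate (n nonnegative reals).
#' @param s received input vector (m nonnegative reals).
#' @return numeric vector of m fractional errors.
#' @export
fractional_errors <- function(basis, x_hat, s) {
  mu <- mean_input(basis, x_hat)
  s <- as.numeric(s)
  if (length(s) != length(mu)) stop_dim("inputs", length(mu), length(s))
  s / mu - 1
}

#' Poisson log-likelihood of an estimate
#'
#' `sum_j [ s_j log(lambda_j) - lambda_j ]` with `lambda = W x_hat + w0`;
#' the data-only `log(s_j!)` terms are dropped. The divisive dynamics
#' perform gradient ascent on this function.
#'
#' @inheritParams fractional_errors
#' @return a single real.
#' @export
poisson_loglik <- function(basis, x_hat, s) {
  lam <- mean_input(basis, x_hat)
  sum(s * log(lam) - lam)
}

#' Effective input weights under divisive feedback
#'
#' The response-dependent weighting each input receives once the population
#' activity `r` divides it: `W[j,i] / (sum_k W[j,k] r[k] + w0)`. At `r = 0`
#' this is `W / w0`; every entry shrinks as activity on overlapping features
#' grows, which is how the feedback reshapes selectivity.
#'
#' @param basis a [feature_basis()].
#' @param r population activity, n nonnegative reals.
#' @return an m x n matrix.
#' @export
effective_weights <- function(basis, r) {
  denom <- mean_input(basis, r)
  basis$weights / denom
}

new_state <- function(x_hat, iter = 0L, converged = FALSE,
                      loglik_trace = numeric(0)) {
  list(x_hat = x_hat, iter = iter, converged = converged,
       loglik_trace = loglik_trace)
}

#' One step of the divisive (Poisson) estimator dynamics
#'
#' Euler update `x_hat <- x_hat + eta * t(W) %*% fractional_errors`, clamped
#' at zero when the configuration requests nonnegativity.
#'
#' @param basis a [feature_basis()].
#' @param state a list with at least `x_hat` and `iter` (as returned by
#'   previous steps or `list(x_hat = x0, iter = 0L)`).
#' @param s input vector.
#' @param config an [estimator_config()].
#' @return the updated state.
#' @export
divisive_step <- function(basis, state, s, config = estimator_config()) {
  eta <- config$eta %||% default_eta(basis)
  g <- drop(crossprod(basis$weights, fractional_errors(basis, state$x_hat, s)))
  x <- state$x_hat + eta * g
  if (any(!is.finite(x)))
    stop(sprintf("non-finite update for feature %d",
                 which(!is.finite(x))[1]), call. = FALSE)
  if (config$clamp_nonnegative) x <- pmax(x, 0)
  state$x_hat <- x
  state$iter <- state$iter + 1L
  state
}

#' One step of the subtractive (Gaussian) estimator dynamics
#'
#' As [divisive_step()] but driven by absolute prediction errors
#' `s_j - (sum_k W[j,k] x_hat[k] + w0)`.
#'
#' @inheritParams divisive_step
#' @return the updated state.
#' @export
subtractive_step <- function(basis, state, s, config = estimator_config()) {
  eta <- config$eta %||% default_eta(basis)
  err <- as.numeric(s) - mean_input(basis, state$x_hat)
  x <- state$x_hat + eta * drop(crossprod(basis$weights, err))
  if (any(!is.finite(x)))
    stop(sprintf("non-finite update for feature %d",
                 which(!is.finite(x))[1]), call. = FALSE)
  if (config$clamp_nonnegative) x <- pmax(x, 0)
  state$x_hat <- x
  state$iter <- state$iter + 1L
  state
}

#' Run the estimator dynamics to convergence
#'
#' Iterates [divisive_step()] or [subtractive_step()] from `x0` (default:
#' all zeros, matching how encoded features are initialized) until the
#' largest per-step change drops below `config$tol` or `config$max_iters`
#' is reached. Non-convergence is flagged on the returned object, not
#' raised as an error.
#'
#' @param basis a [feature_basis()].
#' @param s input vector.
#' @param config an [estimator_config()].
#' @param mode `"divisive"` (Poisson / fractional errors) or
#'   `"subtractive"` (Gaussian / absolute errors).
#' @param x0 starting estimate (default zeros).
#' @return a [feature_fit] object.
#' @export
run_to_convergence <- function(basis, s, config = estimator_config(),
                               mode = c("divisive", "subtractive"),
                               x0 = NULL) {
  mode <- match.arg(mode)
  n <- ncol(basis$weights)
  x0 <- x0 %||% numeric(n)
  if (length(x0) != n) stop_dim("features", n, length(x0))
  state <- new_state(as.numeric(x0))
  step_fn <- if (mode == "divisive") divisive_step else subtractive_step
  ll <- numeric(0)
  converged <- FALSE
  for (it in seq_len(config$max_iters)) {
    prev <- state$x_hat
    state <- step_fn(basis, state, s, config)
    if (it %% config$loglik_every == 0L)
      ll <- c(ll, poisson_loglik(basis, state$x_hat, s))
    if (max(abs(state$x_hat - prev)) < config$tol) {
      converged <- TRUE
      break
    }
  }
  ll <- c(ll, poisson_loglik(basis, state$x_hat, s))
  new_feature_fit(x_hat = state$x_hat, basis = basis, s = as.numeric(s),
                  method = mode, solver = "dynamics",
                  converged = converged, iter = state$iter,
                  loglik_trace = ll, config = config)
}

#' Batched divisive maximum-likelihood solver
#'
#' Computes the fixed point of the divisive dynamics -- the nonnegative
#' maximum-likelihood feature estimate under the linear-Poisson model --
#' with a multiplicative (EM) update that accounts for the fixed background:
#' `x <- x * (t(W) %*% (s / lambda)) / colSums(W)` with
#' `lambda = W x + w0`. The update shares its fixed points with the
#' gradient dynamics (interior zeros of the likelihood gradient; boundary
#' coordinates decay to zero exactly when their gradient is negative) and
#' ascends the likelihood monotonically, but converges in far fewer
#' iterations, and it vectorizes over stimuli: `s` may be an m x N matrix
#' of independent inputs, solved as one sequence of matrix products.
#'
#' @param basis a [feature_basis()].
#' @param s input vector or m x N matrix (one stimulus per column).
#' @param tol relative convergence tolerance on the per-iteration change.
#' @param max_iter iteration cap.
#' @param x0 optional starting value (vector or n x N matrix); default is a
#'   strictly positive scalar estimate per column.
#' @param relax over-relaxation exponent on the multiplicative factor
#'   (exponent-accelerated Richardson-Lucy); 1 is the plain EM update,
#'   values up to ~1.9 speed up the geometric tail on strongly overlapping
#'   bases without changing the fixed points.
#' @return an n x N matrix of estimates (a vector if `s` was a vector),
#'   with attributes `iterations` and `converged` (logical per column).
#' @export
divisive_ml <- function(basis, s, tol = 1e-10, max_iter = 20000L,
                        x0 = NULL, relax = 1) {
  stopifnot(relax >= 1, relax < 2)
  W <- basis$weights
  w0 <- basis$background
  was_vec <- is.null(dim(s))
  S <- as.matrix(s)
  m <- nrow(W); n <- ncol(W); N <- ncol(S)
  if (nrow(S) != m) stop_dim("inputs", m, nrow(S))
  cs <- colSums(W)
  dead <- cs <= 0            # undriven features stay at zero
  cs[dead] <- 1
  if (is.null(x0)) {
    x_scalar <- pmax((colSums(S) - m * w0) / sum(W), 1e-6)
    X <- matrix(rep(x_scalar, each = n), n, N)
  } else {
    X <- matrix(as.numeric(x0), n, N)
  }
  X[dead, ] <- 0
  active <- seq_len(N)
  iters <- integer(N)
  it <- 0L
  check_every <- 10L                 # amortize the per-column max scan
  while (length(active) > 0L && it < max_iter) {
    it <- it + 1L
    Xa <- X[, active, drop = FALSE]
    lam <- W %*% Xa + w0
    mult <- crossprod(W, S[, active, drop = FALSE] / lam) / cs
    mult[dead, ] <- 1
    Xn <- if (relax == 1) Xa * mult else Xa * mult^relax
    X[, active] <- Xn
    iters[active] <- it
    if (it %% check_every == 0L || it == max_iter) {
      d <- apply(abs(Xn - Xa), 2, max)
      scale <- 1 + apply(Xn, 2, max)
      active <- active[!(d < tol * scale)]
    }
  }
  conv <- rep(TRUE, N)
  conv[active] <- FALSE
  if (was_vec) {
    out <- drop(X)
  } else {
    out <- X
  }
  attr(out, "iterations") <- iters
  attr(out, "converged") <- conv
  out
}

#' Batched divisive gradient dynamics
#'
#' Vectorized projected gradient ascent
#' `x <- max(x + eta * t(W) %*% (s / lambda - 1), 0)` from `x0` (default
#' zeros) -- the estimator dynamics themselves, run over many stimuli at
#' once. On bases with strongly overlapping features the likelihood is
#' concave but has a nearly flat optimal face; unlike [divisive_ml()]
#' (whose multiplicative updates sharpen estimates onto few features), the
#' dynamics initialized at zero settle on the smooth representative of that
#' face, which is the operating point at which graded, bell-shaped tuning
#' curves and their contextual shifts arise. Stops when every column's
#' largest per-step change falls below `tol`.
#'
#' @inheritParams divisive_ml
#' @param eta update rate (default `1e-3 / max(colSums(W))`).
#' @return n x N matrix with attributes `iterations`, `converged`.
#' @export
divisive_dynamics <- function(basis, s, eta = NULL, tol = 1e-6,
                              max_iter = 20000L, x0 = NULL) {
  W <- basis$weights
  w0 <- basis$background
  eta <- eta %||% default_eta(basis)
  was_vec <- is.null(dim(s))
  S <- as.matrix(s)
  m <- nrow(W); n <- ncol(W); N <- ncol(S)
  if (nrow(S) != m) stop_dim("inputs", m, nrow(S))
  X0 <- if (is.null(x0)) matrix(0, n, N) else matrix(as.numeric(x0), n, N)
  res <- divisive_dynamics_cpp(W, w0, S, X0, eta, tol,
                               as.integer(max_iter), 25L)
  out <- if (was_vec) drop(res$X) else res$X
  attr(out, "iterations") <- as.integer(res$iterations)
  attr(out, "converged") <- as.logical(res$converged)
  out
}

#' Batched subtractive (nonnegative least-squares) solver
#'
#' Computes the clamped fixed point of the subtractive dynamics -- the
#' nonnegative least-squares solution of `W x + w0 ~ s` -- by accelerated
#' projected gradient (FISTA) with step `1 / ||W||_2^2`. Vectorizes over
#' stimuli like [divisive_ml()].
#'
#' @inheritParams divisive_ml
#' @return an n x N matrix (vector for vector input) with attributes
#'   `iterations` and `converged`.
#' @export
subtractive_nnls <- function(basis, s, tol = 1e-10, max_iter = 50000L,
                             x0 = NULL) {
  W <- basis$weights
  w0 <- basis$background
  was_vec <- is.null(dim(s))
  S <- as.matrix(s) - w0
  m <- nrow(W); n <- ncol(W); N <- ncol(S)
  if (nrow(S) != m) stop_dim("inputs", m, nrow(S))
  alpha <- 1 / norm(W, "2")^2
  X <- if (is.null(x0)) matrix(0, n, N) else matrix(as.numeric(x0), n, N)
  Y <- X
  tk <- 1
  it <- 0L
  conv <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    Xn <- pmax(Y + alpha * crossprod(W, S - W %*% Y), 0)
    tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
    d <- max(abs(Xn - X))
    Y <- Xn + ((tk - 1) / tn) * (Xn - X)
    X <- Xn
    tk <- tn
    if (d < tol * (1 + max(abs(X)))) {
      conv <- TRUE
      break
    }
  }
  out <- if (was_vec) drop(X) else X
  attr(out, "iterations") <- it
  attr(out, "converged") <- conv
  out
}

#' Closed-form subtractive estimate
#'
#' The unconstrained fixed point of the subtractive dynamics is the
#' least-squares readout `(W'W)^-1 W' (s - w0)`; the background is removed
#' first so that noiseless inputs recover the generating features exactly.
#' The returned vector is clamped at zero (features are intensities); the
#' raw solution is attached as attribute `"unclamped"`.
#'
#' @param basis a [feature_basis()].
#' @param s input vector.
#' @param ridge optional nonnegative ridge added to `W'W` for singular
#'   bases.
#' @return clamped estimate with attribute `unclamped`.
#' @export
subtractive_closed_form <- function(basis, s, ridge = 0) {
  W <- basis$weights
  G <- crossprod(W)
  if (ridge > 0) G <- G + diag(ridge, ncol(W))
  ok <- tryCatch({
    sol <- solve(G, crossprod(W, as.numeric(s) - basis$background))
    TRUE
  }, error = function(e) FALSE)
  if (!ok)
    stop("W'W is singular; supply a positive `ridge`", call. = FALSE)
  sol <- drop(sol)
  out <- pmax(sol, 0)
  attr(out, "unclamped") <- sol
  out
}
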