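#' Estimate stimulus features from a noisy input
#'
#' The package's modelling front door. Given a generative basis and one
#' received input vector, returns the steady-state feature estimate under
#' either noise model:
#' \describe{
#'   \item{`"divisive"`}{nonnegative maximum likelihood under the
#'     linear-Poisson model, the fixed point of the fractional-prediction-
#'     error dynamics;}
#'   \item{`"subtractive"`}{nonnegative least squares, the fixed point of
#'     the absolute-error (constant-Gaussian-noise) dynamics.}
#' }
#' Solvers: `"dynamics"` integrates the gradient dynamics themselves
#' (reference implementation, [run_to_convergence()]); `"multiplicative"`
#' ([divisive_ml()]) and `"projected_gradient"` ([subtractive_nnls()]) reach
#' the same fixed points much faster; `"closed_form"` is the unclamped
#' least-squares solution ([subtractive_closed_form()], subtractive only).
#' `"auto"` picks the fast solver for each method.
#'
#' @param basis a [feature_basis()].
#' @param s received input vector (m nonnegative reals).
#' @param method `"divisive"` or `"subtractive"`.
#' @param solver see Details.
#' @param config an [estimator_config()]; its `tol` and `max_iters` also
#'   govern the fast solvers.
#' @param x0 optional starting estimate (dynamics solver).
#' @return a `feature_fit` object: the estimate is available through
#'   [coef()], predicted mean inputs through [fitted()], fractional or
#'   absolute prediction errors through [residuals()], and the Poisson
#'   log-likelihood through [logLik()].
#' @examples
#' b <- build_basis("paired", n_features = 4, background = 1)
#' s <- sample_inputs(b, c(2, 0, 1, 0), seed = 1)
#' fit <- feature_estimate(b, s)
#' coef(fit)
#' @export
feature_estimate <- function(basis, s,
                             method = c("divisive", "subtractive"),
                             solver = c("auto", "dynamics", "multiplicative",
                                        "projected_gradient", "closed_form"),
                             config = estimator_config(), x0 = NULL) {
  method <- match.arg(method)
  solver <- match.arg(solver)
  if (solver == "auto")
    solver <- if (method == "divisive") "multiplicative"
              else "projected_gradient"
  if (solver == "dynamics")
    return(run_to_convergence(basis, s, config, mode = method, x0 = x0))
  if (solver == "multiplicative") {
    if (method != "divisive")
      stop("the multiplicative solver applies to the divisive method",
           call. = FALSE)
    x <- divisive_ml(basis, s, tol = min(config$tol, 1e-10),
                     max_iter = config$max_iters, x0 = x0)
  } else if (solver == "projected_gradient") {
    if (method != "subtractive")
      stop("projected_gradient applies to the subtractive method",
           call. = FALSE)
    x <- subtractive_nnls(basis, s, tol = min(config$tol, 1e-10),
                          max_iter = config$max_iters, x0 = x0)
  } else {
    if (method != "subtractive")
      stop("closed_form applies to the subtractive method", call. = FALSE)
    x <- subtractive_closed_form(basis, s)
  }
  conv <- attr(x, "converged") %||% TRUE
  iters <- attr(x, "iterations") %||% NA_integer_
  xv <- as.numeric(x)
  new_feature_fit(x_hat = xv, basis = basis, s = as.numeric(s),
                  method = method, solver = solver,
                  converged = all(conv), iter = iters[1],
                  loglik_trace = poisson_loglik(basis, xv, s),
                  config = config)
}

new_feature_fit <- function(x_hat, basis, s, method, solver, converged,
                            iter, loglik_trace, config) {
  structure(list(x_hat = x_hat, basis = basis, s = s, method = method,
                 solver = solver, converged = converged, iter = iter,
                 loglik_trace = loglik_trace, config = config),
            class = "feature_fit")
}

#' @export
print.feature_fit <- function(x, ...) {
  cat(sprintf("feature_fit (%s, %s solver): %d features, %d inputs\n",
              x$method, x$solver, length(x$x_hat), length(x$s)))
  cat(sprintf("  converged: %s after %s iterations\n",
              x$converged, format(x$iter)))
  cat("  estimate: ")
  utils::str(x$x_hat, give.head = FALSE)
  invisible(x)
}

#' @export
coef.feature_fit <- function(object, ...) object$x_hat

#' @export
fitted.feature_fit <- function(object, ...)
  mean_input(object$basis, object$x_hat)

#' @export
residuals.feature_fit <- function(object,
                                  type = c("fractional", "absolute"), ...) {
  type <- match.arg(type)
  if (type == "fractional")
    fractional_errors(object$basis, object$x_hat, object$s)
  else
    object$s - fitted(object)
}

#' @export
logLik.feature_fit <- function(object, ...) {
  ll <- poisson_loglik(object$basis, object$x_hat, object$s)
  structure(ll, df = sum(object$x_hat > 0), class = "logLik")
}

#' @export
summary.feature_fit <- function(object, ...) {
  fr <- residuals(object, "fractional")
  out <- list(method = object$method, solver = object$solver,
              converged = object$converged, iter = object$iter,
              n_active = sum(object$x_hat > 0),
              n_features = length(object$x_hat),
              loglik = poisson_loglik(object$basis, object$x_hat, object$s),
              max_abs_fractional_error = max(abs(fr)),
              stationarity = max(abs(
                crossprod(object$basis$weights, fr))))
  class(out) <- "summary.feature_fit"
  out
}

#' @export
print.summary.feature_fit <- function(x, ...) {
  cat(sprintf("%s estimate (%s solver)\n", x$method, x$solver))
  cat(sprintf("  %d of %d features active; converged: %s (iter %s)\n",
              x$n_active, x$n_features, x$converged, format(x$iter)))
  cat(sprintf("  Poisson log-likelihood: %.6g\n", x$loglik))
  cat(sprintf("  max |fractional error|: %.3g; stationarity |W'e|_max: %.3g\n",
              x$max_abs_fractional_error, x$stationarity))
  invisible(x)
}
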