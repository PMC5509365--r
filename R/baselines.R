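#' Linear-nonlinear (LN) response model
#'
#' The null model for contextual effects: each output unit linearly filters
#' the inputs and applies a static rectifier,
#' `r_i = max(sum_j V[j,i] s_j + v0_i, 0)`.
#'
#' @param filters m x n matrix of linear weights `V`.
#' @param offset scalar or n-vector of offsets `v0`.
#' @return an object of class `ln_model`.
#' @export
ln_model <- function(filters, offset = 0) {
  filters <- as.matrix(filters)
  if (any(!is.finite(filters)) || any(!is.finite(offset)))
    stop("LN parameters must be finite", call. = FALSE)
  if (!length(offset) %in% c(1L, ncol(filters)))
    stop_dim("offset", ncol(filters), length(offset))
  structure(list(filters = filters,
                 offset = rep_len(as.numeric(offset), ncol(filters))),
            class = "ln_model")
}

#' @export
print.ln_model <- function(x, ...) {
  cat(sprintf("ln_model: %d inputs -> %d units, rectifier nonlinearity\n",
              nrow(x$filters), ncol(x$filters)))
  invisible(x)
}

#' Evaluate an LN model
#'
#' @param model an [ln_model()].
#' @param s input vector (m) or m x N matrix.
#' @return n-vector of responses, or n x N matrix for matrix input.
#' @export
ln_response <- function(model, s) {
  stopifnot(inherits(model, "ln_model"))
  was_vec <- is.null(dim(s))
  S <- as.matrix(s)
  if (nrow(S) != nrow(model$filters))
    stop_dim("inputs", nrow(model$filters), nrow(S))
  R <- pmax(crossprod(model$filters, S) + model$offset, 0)
  if (was_vec) drop(R) else R
}

#' @export
predict.ln_model <- function(object, newdata, ...) ln_response(object, newdata)

#' @export
coef.ln_model <- function(object, ...)
  list(filters = object$filters, offset = object$offset)

#' Fit an LN model to target responses
#'
#' Least-squares fit of the linear stage (weights and offset) to the given
#' stimulus/response pairs. The rectifier makes the exact problem
#' nonconvex; by default the linear stage is fitted by ordinary (ridge-
#' regularized) least squares on all pairs and the rectifier applied at
#' evaluation only -- adequate when the targets are predominantly
#' supra-threshold, as the divisive model's responses are. With
#' `refit_active = TRUE` the fit is repeated on the active set (pairs whose
#' current prediction is positive) until the set stabilizes.
#'
#' @param stimuli m x N matrix of inputs (or list of m-vectors).
#' @param targets n x N matrix of responses to match (or list).
#' @param ridge nonnegative ridge on the Gram matrix, relative to the mean
#'   of its diagonal (default 1e-6); with fewer than m + 1 distinct stimuli
#'   a positive ridge is required.
#' @param refit_active iterate the fit on the rectifier's active set.
#' @param max_refits cap on the active-set iterations.
#' @return an [ln_model()].
#' @export
fit_ln <- function(stimuli, targets, ridge = 1e-6, refit_active = FALSE,
                   max_refits = 10L) {
  S <- if (is.list(stimuli)) do.call(cbind, stimuli) else as.matrix(stimuli)
  R <- if (is.list(targets)) do.call(cbind, targets) else as.matrix(targets)
  if (ncol(S) != ncol(R))
    stop_dim("stimulus/response pairs", ncol(S), ncol(R))
  m <- nrow(S); n <- nrow(R); N <- ncol(S)
  A <- rbind(S, 1)                      # (m+1) x N design with intercept
  solve_ls <- function(cols) {
    G <- tcrossprod(A[, cols, drop = FALSE])
    if (ridge > 0) G <- G + diag(ridge * mean(diag(G)), m + 1L)
    ok <- tryCatch({
      B <- solve(G, tcrossprod(A[, cols, drop = FALSE],
                               R[, cols, drop = FALSE]))
      TRUE
    }, error = function(e) FALSE)
    if (!ok)
      stop("rank-deficient design; supply a positive `ridge`",
           call. = FALSE)
    B                                    # (m+1) x n
  }
  B <- solve_ls(seq_len(N))
  if (refit_active) {
    # per-unit active-set refit: keep pairs the rectifier leaves active
    for (i in seq_len(n)) {
      prev <- NULL
      for (k in seq_len(max_refits)) {
        pred <- drop(crossprod(A, B[, i]))
        act <- which(pred > 0 | R[i, ] > 0)
        if (length(act) < m + 1L) break
        if (!is.null(prev) && identical(act, prev)) break
        Gi <- tcrossprod(A[, act, drop = FALSE])
        Gi <- Gi + diag(ridge * mean(diag(Gi)), m + 1L)
        B[, i] <- solve(Gi, A[, act, drop = FALSE] %*% R[i, act])
        prev <- act
      }
    }
  }
  ln_model(B[seq_len(m), , drop = FALSE], B[m + 1L, ])
}
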