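#' Response-model adapters
#'
#' The probes accept any deterministic steady-state response model: a
#' function mapping an m x N input matrix to an n x N response matrix, or
#' an [ln_model()]. These constructors wrap the package's estimators and
#' network as such models (responses are the steady-state feature
#' estimates; all trial-to-trial noise lives in the input sampler).
#'
#' @param basis a [feature_basis()].
#' @param tol,max_iter,relax solver controls (see [divisive_ml()] /
#'   [subtractive_nnls()]).
#' @param engine `"ml"` (multiplicative solver; selects the sharp,
#'   explaining-away-complete representative of the maximum-likelihood
#'   set) or `"dynamics"` ([divisive_dynamics()]; the estimator dynamics
#'   from zero, whose quasi-converged estimates stay graded on strongly
#'   overlapping bases -- use this for tuning-curve protocols).
#' @param eta update rate for the dynamics engine.
#' @return a function `f(S)` returning an n x N response matrix.
#' @export
divisive_model <- function(basis, tol = 1e-8, max_iter = 5000L,
                           relax = 1.9,
                           engine = c("ml", "dynamics"), eta = NULL) {
  force(basis)
  engine <- match.arg(engine)
  if (engine == "dynamics") {
    function(S) {
      X <- divisive_dynamics(basis, S, eta = eta, tol = tol,
                             max_iter = max_iter)
      attributes(X)[c("iterations", "converged")] <- NULL
      X
    }
  } else {
    function(S) {
      X <- divisive_ml(basis, S, tol = tol, max_iter = max_iter,
                       relax = relax)
      attributes(X)[c("iterations", "converged")] <- NULL
      X
    }
  }
}

#' @rdname divisive_model
#' @param clamp if `TRUE` the subtractive responses are the nonnegative
#'   least-squares fixed point of the clamped dynamics; if `FALSE` they are
#'   the unconstrained linear least-squares readout
#'   `(W'W + ridge I)^-1 W'(s - w0)` -- the fully linear subtractive model,
#'   whose surround suppression is by construction independent of where in
#'   the receptive field a stimulus falls.
#' @param ridge diagonal loading for the unclamped readout (the paired
#'   basis is circulant-singular).
#' @export
subtractive_model <- function(basis, tol = 1e-8, max_iter = 50000L,
                              clamp = TRUE, ridge = 1e-6) {
  force(basis)
  if (clamp) {
    function(S) {
      X <- subtractive_nnls(basis, S, tol = tol, max_iter = max_iter)
      attributes(X)[c("iterations", "converged")] <- NULL
      X
    }
  } else {
    W <- basis$weights
    G <- crossprod(W) + diag(ridge, ncol(W))
    function(S) solve(G, crossprod(W, as.matrix(S) - basis$background))
  }
}

# evaluate any supported model on an m x N matrix -> n x N matrix
eval_model <- function(model, S) {
  S <- as.matrix(S)
  R <- if (inherits(model, "ln_model")) ln_response(model, S)
       else if (is.function(model)) model(S)
       else stop("model must be a function or an ln_model", call. = FALSE)
  as.matrix(R)
}

#' Receptive fields by reverse correlation
#'
#' Estimates linear receptive fields from randomized stimulation:
#' `rf = Qss^-1 qrs` with raw (uncentered) second moments
#' `(Qss)_ij = <s_i s_j>` and `(qrs)_ij = <s_i r_j>` averaged over
#' `n_presentations` draws from `stimulus_sampler`. If the moment matrix's
#' condition number exceeds 1e12 the supplied `ridge` is added to its
#' diagonal; a singular moment matrix without ridge is an error.
#'
#' @param model response model (see [divisive_model()]).
#' @param stimulus_sampler function `f(N)` returning an m x N stimulus
#'   matrix, or an already-drawn m x N matrix; `rf_from_data` additionally
#'   accepts precomputed responses, for reusing one expensive model
#'   evaluation across several analyses.
#' @param n_presentations number of stimulus draws.
#' @param neuron_ids which output units to map (default: all).
#' @param ridge diagonal loading used when the moments are ill-conditioned.
#' @param centered use centered (co)moments instead of the raw ones
#'   (default `FALSE`: the raw formula is the standard one even though
#'   sparse nonnegative stimuli make the choice consequential).
#' @param seed RNG seed; with the same seed the estimate is reproducible
#'   bit for bit.
#' @param context optional label stored on the result.
#' @return an `rf_estimate`: `rf` (m x length(neuron_ids) matrix),
#'   `neuron_ids`, `n_presentations`, `context`.
#' @export
reverse_correlation_rf <- function(model, stimulus_sampler, n_presentations,
                                   neuron_ids = NULL, ridge = 1e-6,
                                   centered = FALSE, seed = NULL,
                                   context = NULL) {
  if (n_presentations < 1L) stop("n_presentations must be >= 1",
                                 call. = FALSE)
  S <- if (is.matrix(stimulus_sampler)) stimulus_sampler
       else with_seed(seed, stimulus_sampler(n_presentations))
  S <- as.matrix(S)
  R <- eval_model(model, S)
  rf_from_data(S, R, neuron_ids = neuron_ids, ridge = ridge,
               centered = centered, context = context)
}

#' @rdname reverse_correlation_rf
#' @param stimuli m x N stimulus matrix (already drawn).
#' @param responses n x N matrix of the model's responses to `stimuli`.
#' @export
rf_from_data <- function(stimuli, responses, neuron_ids = NULL,
                         ridge = 1e-6, centered = FALSE, context = NULL) {
  S <- as.matrix(stimuli)
  R <- as.matrix(responses)
  neuron_ids <- neuron_ids %||% seq_len(nrow(R))
  N <- ncol(S)
  if (centered) {
    S <- S - rowMeans(S)
    R <- R - rowMeans(R)
  }
  Qss <- tcrossprod(S) / N
  qrs <- tcrossprod(S, R[neuron_ids, , drop = FALSE]) / N
  kap <- kappa(Qss, exact = FALSE)
  if (!is.finite(kap) || kap > 1e12) {
    if (ridge <= 0)
      stop("stimulus moment matrix is singular; supply a positive ridge",
           call. = FALSE)
    Qss <- Qss + diag(ridge, nrow(Qss))
  }
  rf <- solve(Qss, qrs)
  structure(list(rf = rf, neuron_ids = neuron_ids,
                 n_presentations = N, context = context),
            class = "rf_estimate")
}

#' @export
print.rf_estimate <- function(x, ...) {
  cat(sprintf("rf_estimate: %d units, %d inputs, %d presentations%s\n",
              ncol(x$rf), nrow(x$rf), x$n_presentations,
              if (is.null(x$context)) "" else paste0(" [", x$context, "]")))
  invisible(x)
}

#' Contextual tuning curves
#'
#' Mean steady-state response of every unit as a function of a 1-D
#' stimulus index. Stimulus `i` activates the inputs with the profile of
#' feature `i`: means `W[, i] + w0`, drawn independently Poisson on each
#' trial. A context is either a held-constant receptor
#' (`list(receptor =, value =)`, the receptor's activation replaced by
#' `value` after the draw) or a numeric m-vector added to the means before
#' the draw (a constant mask built from background features).
#'
#' @param model response model.
#' @param basis the generative [feature_basis()] defining the stimulus
#'   protocol.
#' @param stimulus_values which feature indices to present (default all).
#' @param context_mask `NULL`, a `list(receptor =, value =)`, or an
#'   m-vector.
#' @param trials Poisson trials averaged per stimulus value.
#' @param seed RNG seed.
#' @param context optional label.
#' @return a `tuning_curve_set`: `stimulus_values`, `responses` (values x
#'   units matrix of trial means), `context`, `rescaled`, `trials`.
#' @export
tuning_curve <- function(model, basis, stimulus_values = NULL,
                         context_mask = NULL, trials = 200L, seed = NULL,
                         context = NULL) {
  W <- basis$weights
  w0 <- basis$background
  stimulus_values <- stimulus_values %||% seq_len(ncol(W))
  m <- nrow(W)
  nv <- length(stimulus_values)
  add <- numeric(m)
  held <- NULL
  if (is.numeric(context_mask)) {
    if (length(context_mask) != m) stop_dim("mask", m, length(context_mask))
    add <- context_mask
  } else if (is.list(context_mask)) {
    held <- context_mask
  }
  mu <- W[, stimulus_values, drop = FALSE] + w0 + add   # m x nv means
  S <- with_seed(seed, {
    draws <- matrix(stats::rpois(m * nv * trials,
                                 rep(as.numeric(mu), times = trials)),
                    nrow = m)
    draws
  })
  # columns ordered: all nv stimuli for trial 1, then trial 2, ...
  if (!is.null(held)) S[held$receptor, ] <- held$value
  R <- eval_model(model, S)
  stim_of_col <- rep(seq_len(nv), times = trials)
  resp <- rowsum(t(R), stim_of_col) / trials   # nv x n_units
  dimnames(resp) <- NULL
  structure(list(stimulus_values = stimulus_values, responses = resp,
                 context = context, rescaled = FALSE, trials = trials),
            class = "tuning_curve_set")
}

#' @export
print.tuning_curve_set <- function(x, ...) {
  cat(sprintf("tuning_curve_set: %d stimulus values x %d units, %d trials%s%s\n",
              nrow(x$responses), ncol(x$responses), x$trials,
              if (x$rescaled) " (rescaled)" else "",
              if (is.null(x$context)) "" else paste0(" [", x$context, "]")))
  invisible(x)
}

#' Rescale tuning curves to zero mean, unit standard deviation
#'
#' Puts curves measured in different contexts on a common scale so that
#' shape changes (shifts) can be compared independently of gain. Flat
#' curves are mapped to zero.
#'
#' @param tc a `tuning_curve_set`.
#' @return the rescaled `tuning_curve_set`.
#' @export
rescale_curves <- function(tc) {
  stopifnot(inherits(tc, "tuning_curve_set"))
  tc$responses <- apply(tc$responses, 2, function(y) {
    s <- stats::sd(y)
    if (s < 1e-12) rep(0, length(y)) else (y - mean(y)) / s
  })
  tc$rescaled <- TRUE
  tc
}

#' Fit a linear readout (decoder)
#'
#' Least-squares reconstruction map from population responses back to the
#' inputs: `U = <s_c r_c'> <r_c r_c'>^-1` with `s_c = s - <s>`,
#' `r_c = r - <r>`. A singular response covariance triggers a warning and
#' diagonal loading.
#'
#' @param stimuli m x N matrix of inputs.
#' @param responses n x N matrix of responses.
#' @param ridge diagonal loading for singular response covariance.
#' @param context optional label.
#' @return a `readout_filter`: `U` (m x n), `s_mean`, `r_mean`, `context`.
#' @export
fit_readout <- function(stimuli, responses, ridge = 1e-8, context = NULL) {
  S <- as.matrix(stimuli)
  R <- as.matrix(responses)
  if (ncol(S) != ncol(R)) stop_dim("samples", ncol(S), ncol(R))
  N <- ncol(S)
  s_mean <- rowMeans(S)
  r_mean <- rowMeans(R)
  Sc <- S - s_mean
  Rc <- R - r_mean
  Crr <- tcrossprod(Rc) / N
  Csr <- tcrossprod(Sc, Rc) / N
  U <- tryCatch(t(solve(Crr, t(Csr))), error = function(e) {
    warning("singular response covariance; adding ridge", call. = FALSE)
    t(solve(Crr + diag(ridge, nrow(Crr)), t(Csr)))
  })
  structure(list(U = U, s_mean = s_mean, r_mean = r_mean,
                 context = context),
            class = "readout_filter")
}

#' @export
print.readout_filter <- function(x, ...) {
  cat(sprintf("readout_filter: %d units -> %d inputs%s\n",
              ncol(x$U), nrow(x$U),
              if (is.null(x$context)) "" else paste0(" [", x$context, "]")))
  invisible(x)
}

#' Normalized reconstruction error
#'
#' Root-mean-square error of the linear reconstruction
#' `s_hat = U (r - <r>) + <s>`, normalized by the rms of the centered
#' stimulus -- so that the trivial decoder `U = 0` scores exactly 1 and
#' perfect reconstruction scores 0. Evaluation-set means are used.
#'
#' @param readout a `readout_filter` (or a bare m x n matrix `U`).
#' @param stimuli m x N matrix of the true inputs.
#' @param responses n x N matrix of responses.
#' @return a single nonnegative real.
#' @export
reconstruction_error <- function(readout, stimuli, responses) {
  U <- if (inherits(readout, "readout_filter")) readout$U else as.matrix(readout)
  S <- as.matrix(stimuli)
  R <- as.matrix(responses)
  Sc <- S - rowMeans(S)
  Rc <- R - rowMeans(R)
  err <- Sc - U %*% Rc
  sqrt(mean(err^2)) / sqrt(mean(Sc^2))
}

# peak location of a curve by 3-point parabolic interpolation around the
# argmax; circular = TRUE treats the index axis as a ring
peak_location <- function(y, circular = FALSE) {
  n <- length(y)
  k <- which.max(y)
  idx <- if (circular) c((k - 2) %% n + 1, k, k %% n + 1)
         else c(max(k - 1, 1), k, min(k + 1, n))
  if (idx[1] == idx[2] || idx[2] == idx[3]) return(as.numeric(k))
  y3 <- y[idx]
  denom <- y3[1] - 2 * y3[2] + y3[3]
  if (abs(denom) < 1e-300) return(as.numeric(k))
  delta <- 0.5 * (y3[1] - y3[3]) / denom
  delta <- max(min(delta, 0.5), -0.5)
  k + delta
}

#' Cross-context shift and difference metrics
#'
#' Quantifies how much tuning curves (or receptive fields) change across
#' stimulus contexts. Peaks are located by 3-point parabolic interpolation
#' around the argmax (resolving sub-index shifts); the mean-squared
#' difference is computed between rescaled (zero-mean, unit-sd) curves,
#' averaged over all context pairs.
#'
#' @param curves list of `tuning_curve_set`s (one per context, same
#'   stimulus grid), list of `rf_estimate`s, or list of plain
#'   values-x-units matrices.
#' @param circular treat the stimulus index axis as a ring when computing
#'   peak shifts.
#' @return list with `peak_shift` (units x contexts-1 matrix of signed
#'   shifts relative to the first context, index units) and `msd` (per-unit
#'   mean squared cross-context difference of the rescaled curves).
#' @export
context_shift_metrics <- function(curves, circular = FALSE) {
  mats <- lapply(curves, function(cc) {
    if (inherits(cc, "tuning_curve_set")) cc$responses
    else if (inherits(cc, "rf_estimate")) cc$rf
    else as.matrix(cc)
  })
  n_units <- ncol(mats[[1]])
  nv <- nrow(mats[[1]])
  K <- length(mats)
  stopifnot(K >= 2)
  zs <- lapply(mats, function(M) apply(M, 2, function(y) {
    s <- stats::sd(y)
    if (s < 1e-12) rep(0, length(y)) else (y - mean(y)) / s
  }))
  peaks <- vapply(mats, function(M)
    apply(M, 2, peak_location, circular = circular), numeric(n_units))
  peaks <- matrix(peaks, nrow = n_units)
  shift <- peaks[, -1, drop = FALSE] - peaks[, 1]
  if (circular) shift <- ((shift + nv / 2) %% nv) - nv / 2
  pairs <- utils::combn(K, 2)
  msd <- rowMeans(matrix(vapply(seq_len(ncol(pairs)), function(p) {
    d <- zs[[pairs[1, p]]] - zs[[pairs[2, p]]]
    colMeans(d^2)
  }, numeric(n_units)), nrow = n_units))
  list(peak_shift = shift, msd = msd)
}

#' Write receptive fields / tuning curves as delimited text
#'
#' RF maps are written as a tab-delimited matrix with a JSON sidecar
#' (condition, presentations); tuning curves as a long-format table.
#'
#' @param x an `rf_estimate` or `tuning_curve_set`.
#' @param file path stem.
#' @return `file`, invisibly.
#' @export
write_probe <- function(x, file) {
  if (inherits(x, "rf_estimate")) {
    utils::write.table(x$rf, paste0(file, ".tsv"), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(list(kind = "rf", neuron_ids = x$neuron_ids,
                              n_presentations = x$n_presentations,
                              context = x$context),
                         paste0(file, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  } else if (inherits(x, "tuning_curve_set")) {
    df <- data.frame(stimulus = rep(x$stimulus_values, ncol(x$responses)),
                     unit = rep(seq_len(ncol(x$responses)),
                                each = nrow(x$responses)),
                     response = as.vector(x$responses))
    utils::write.table(df, paste0(file, ".tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(kind = "tuning", trials = x$trials,
                              rescaled = x$rescaled, context = x$context),
                         paste0(file, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  } else stop("unsupported probe object", call. = FALSE)
  invisible(file)
}
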