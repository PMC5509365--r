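#' Parameters of the excitatory/inhibitory rate network
#'
#' The network realizes the divisive estimator with two populations:
#' excitatory units carry fractional prediction errors
#' (`a dr_exc_j/dt = s_j - (w0 + sum_k W[j,k] r_inh_k) r_exc_j`, inhibition
#' multiplying the leak) and inhibitory units integrate the weighted errors
#' and carry the feature estimates
#' (`b dr_inh_i/dt = sum_j W[j,i] (r_exc_j - 1)`). At a steady state the
#' excitatory rate equals the received-over-predicted input ratio (1 for a
#' perfectly predicted input) and the inhibitory rates equal the divisive
#' maximum-likelihood feature estimate. A subtractive variant with constant
#' leak and additive inhibition is provided for comparison (see
#' [simulate_network()]).
#'
#' @param basis a [feature_basis()]; its weights are the connectivity and
#'   its background the leak constant `w0`.
#' @param a excitatory timescale constant (default 0.08).
#' @param b inhibitory integration constant (default 40).
#' @param dt Euler step in seconds; default `1e-4 * a`, well inside the
#'   stability bound (the integrator aborts if `leak * dt / a` exceeds 1).
#' @return an object of class `network_params`.
#' @export
network_params <- function(basis, a = 0.08, b = 40, dt = NULL) {
  stopifnot(inherits(basis, "feature_basis"))
  dt <- dt %||% (1e-4 * a)
  if (a <= 0 || b <= 0 || dt <= 0)
    stop("a, b and dt must be positive", call. = FALSE)
  structure(list(basis = basis, a = a, b = b, dt = dt),
            class = "network_params")
}

#' @export
print.network_params <- function(x, ...) {
  cat(sprintf("network_params: %d exc x %d inh units, a = %g, b = %g, dt = %g\n",
              nrow(x$basis$weights), ncol(x$basis$weights), x$a, x$b, x$dt))
  invisible(x)
}

#' One Euler step of the network dynamics
#'
#' Reference single-step update (the bulk integrator is
#' [simulate_network()]). Both populations are clamped at zero in the
#' divisive mode; in the subtractive mode the excitatory error units are
#' signed and only inhibitory rates are clamped.
#'
#' @param params a [network_params()].
#' @param state list with `r_exc` (m), `r_inh` (n) and `t` (seconds).
#' @param s input vector (m).
#' @param mode `"divisive"` or `"subtractive"`.
#' @return the updated state.
#' @export
network_step <- function(params, state, s,
                         mode = c("divisive", "subtractive")) {
  mode <- match.arg(mode)
  W <- params$basis$weights
  w0 <- params$basis$background
  pred <- w0 + drop(W %*% state$r_inh)
  if (mode == "divisive") {
    if (any(params$dt * pred / params$a > 1))
      stop("unstable integration: leak*dt/a > 1; reduce dt", call. = FALSE)
    dexc <- (s - pred * state$r_exc) / params$a
  } else {
    if (params$dt * w0 / params$a > 1)
      stop("unstable integration: w0*dt/a > 1; reduce dt", call. = FALSE)
    dexc <- (s - w0 * state$r_exc - (pred - w0)) / params$a
  }
  dinh <- drop(crossprod(W, state$r_exc - 1)) / params$b
  r_exc <- state$r_exc + params$dt * dexc
  if (mode == "divisive") r_exc <- pmax(r_exc, 0)
  r_inh <- pmax(state$r_inh + params$dt * dinh, 0)
  if (any(!is.finite(r_exc)) || any(!is.finite(r_inh)))
    stop("non-finite rate: dt too large for stability", call. = FALSE)
  list(r_exc = r_exc, r_inh = r_inh, t = state$t + params$dt)
}

#' Simulate the E/I network
#'
#' Integrates the network from rest (or `init`) for `duration` seconds
#' under a constant, piecewise-constant or time-varying input, recording
#' the state every `record_every` seconds. With `stop_when_steady = TRUE`
#' and a constant input, integration halts once the largest instantaneous
#' rate of change falls below `steady_tol` (units per second); the trace is
#' then truncated at the stopping time.
#'
#' @param params a [network_params()].
#' @param input one of: a numeric m-vector (constant input), a list with
#'   `times` (segment start times, first 0) and `values` (m x K matrix,
#'   piecewise constant), or a function of time returning an m-vector
#'   (sampled every `input_dt` seconds into a piecewise-constant signal).
#' @param duration simulated seconds.
#' @param record_every recording interval (default `duration / 500`).
#' @param mode `"divisive"` or `"subtractive"`.
#' @param init optional list with `r_exc`, `r_inh` starting rates
#'   (default all zeros, step input at t = 0).
#' @param stop_when_steady halt early at a fixed point (constant input).
#' @param steady_tol rate-of-change threshold for `stop_when_steady`.
#' @param input_dt sampling interval for function inputs (default
#'   `record_every`).
#' @return an `ei_trace`: `times`, matrices `r_exc` (records x m) and
#'   `r_inh` (records x n), the parameters and an input descriptor.
#' @export
simulate_network <- function(params, input, duration,
                             record_every = duration / 500,
                             mode = c("divisive", "subtractive"),
                             init = NULL, stop_when_steady = FALSE,
                             steady_tol = 1e-6, input_dt = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "network_params"))
  m <- nrow(params$basis$weights)
  n <- ncol(params$basis$weights)
  if (is.function(input)) {
    input_dt <- input_dt %||% record_every
    times <- seq(0, duration, by = input_dt)
    vals <- vapply(times, function(t) as.numeric(input(t)), numeric(m))
    input <- list(times = times, values = vals)
  }
  if (is.numeric(input)) {
    if (length(input) != m) stop_dim("inputs", m, length(input))
    S <- matrix(input, m, 1)
    breaks <- 0
    descr <- list(kind = "constant", s = input)
  } else {
    S <- as.matrix(input$values)
    breaks <- as.numeric(input$times)
    if (nrow(S) != m) stop_dim("inputs", m, nrow(S))
    if (length(breaks) != ncol(S) || breaks[1] != 0)
      stop("input$times must start at 0 and match ncol(values)",
           call. = FALSE)
    descr <- list(kind = "piecewise", segments = ncol(S))
  }
  exc0 <- init$r_exc %||% numeric(m)
  inh0 <- init$r_inh %||% numeric(n)
  rec_steps <- max(1L, as.integer(round(record_every / params$dt)))
  out <- ei_simulate_cpp(params$basis$weights, params$basis$background,
                         params$a, params$b, params$dt, S, breaks,
                         duration, rec_steps, mode == "subtractive",
                         exc0, inh0, stop_when_steady, steady_tol)
  structure(list(times = out$times, r_exc = out$r_exc, r_inh = out$r_inh,
                 steady = out$steady, params = params, mode = mode,
                 input = descr),
            class = "ei_trace")
}

#' @export
print.ei_trace <- function(x, ...) {
  cat(sprintf("ei_trace (%s): %d records over %.4g s, %d exc / %d inh units%s\n",
              x$mode, length(x$times), max(x$times), ncol(x$r_exc),
              ncol(x$r_inh), if (isTRUE(x$steady)) " [steady]" else ""))
  invisible(x)
}

#' @export
as.data.frame.ei_trace <- function(x, ...) {
  long <- function(M, pop) data.frame(
    time = rep(x$times, ncol(M)),
    unit = rep(seq_len(ncol(M)), each = nrow(M)),
    population = pop, rate = as.vector(M))
  rbind(long(x$r_exc, "exc"), long(x$r_inh, "inh"))
}

#' @export
plot.ei_trace <- function(x, units = NULL, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  ue <- units %||% seq_len(ncol(x$r_exc))
  ui <- units %||% seq_len(ncol(x$r_inh))
  ui <- ui[ui <= ncol(x$r_inh)]
  graphics::matplot(x$times, x$r_exc[, ue, drop = FALSE], type = "l",
                    lty = 1, xlab = "time (s)", ylab = "rate",
                    main = "excitatory (prediction-error) units", ...)
  graphics::matplot(x$times, x$r_inh[, ui, drop = FALSE], type = "l",
                    lty = 1, xlab = "time (s)", ylab = "rate",
                    main = "inhibitory (feature-estimate) units", ...)
  invisible(x)
}

#' Final state of a trace
#'
#' @param trace an `ei_trace`.
#' @return list with `r_exc` and `r_inh` at the last recorded time.
#' @export
final_state <- function(trace) {
  k <- nrow(trace$r_exc)
  list(r_exc = trace$r_exc[k, ], r_inh = trace$r_inh[k, ])
}

#' Two-unit divisive normalization closed form
#'
#' Steady-state response (up to a global constant) of an excitatory unit in
#' the minimal network of two inputs driving one feature:
#' `s1 / max(s1 + s2, w0)` -- the canonical divisive-normalization form
#' with the background as rectification floor. Vectorized over `s1`/`s2`.
#'
#' @param s1,s2 feed-forward inputs.
#' @param w0 background / floor.
#' @return numeric.
#' @export
steady_state_two_unit <- function(s1, s2, w0 = 1) {
  s1 / pmax(s1 + s2, w0)
}

#' Divisive-normalization closed form for simple stimuli
#'
#' For "simple" inputs that do not co-activate overlapping feature
#' detectors, the steady excitatory response is approximately the
#' feed-forward input divided by the rectified input pooled over the unit's
#' neighbourhood (inputs sharing a feature with it):
#' `s_i / max(pooled_i, w0)`, up to one global constant. Not valid for
#' stimuli driving overlapping detectors simultaneously.
#'
#' @param basis a [feature_basis()].
#' @param s input vector.
#' @return m-vector of normalized responses (unit proportionality).
#' @export
steady_state_simple <- function(basis, s) {
  W <- basis$weights
  share <- (tcrossprod(W) > 0) * 1
  pooled <- drop(share %*% as.numeric(s))
  as.numeric(s) / pmax(pooled, basis$background)
}

#' Time for a unit's response to reach a fraction of its maximum
#'
#' First crossing time of `fraction * max(trace)` for one unit, with linear
#' interpolation between recorded samples. Used for time-to-peak
#' (`fraction = 1`) and wave-latency (`fraction = 0.7`) measurements.
#' Returns `NA` if the trace never crosses.
#'
#' @param trace an `ei_trace`.
#' @param unit unit index.
#' @param fraction in (0, 1].
#' @param population `"exc"` or `"inh"`.
#' @return time in seconds, or `NA_real_`.
#' @export
time_to_fraction <- function(trace, unit, fraction = 0.7,
                             population = c("exc", "inh")) {
  population <- match.arg(population)
  y <- if (population == "exc") trace$r_exc[, unit] else trace$r_inh[, unit]
  tt <- trace$times
  peak <- max(y)
  if (peak <= 0) return(NA_real_)
  if (fraction >= 1) {
    # sub-sample peak time by parabolic interpolation: flat maxima make
    # the raw argmax sensitive to rounding noise
    k <- which.max(y)
    if (k == 1L || k == length(y)) return(tt[k])
    denom <- y[k - 1] - 2 * y[k] + y[k + 1]
    if (abs(denom) < 1e-300) return(tt[k])
    delta <- 0.5 * (y[k - 1] - y[k + 1]) / denom
    delta <- max(min(delta, 0.5), -0.5)
    return(tt[k] + delta * (tt[k + 1] - tt[k]))
  }
  target <- fraction * peak
  idx <- which(y >= target)
  if (length(idx) == 0L) return(NA_real_)
  k <- idx[1]
  if (k == 1L) return(tt[1])
  # linear interpolation on the crossing segment
  t0 <- tt[k - 1]; t1 <- tt[k]
  y0 <- y[k - 1]; y1 <- y[k]
  t0 + (target - y0) / (y1 - y0) * (t1 - t0)
}

#' Export a trace as delimited text
#'
#' Writes the long-format trace (time, unit, population, rate) as
#' tab-separated text and a JSON run manifest alongside it.
#'
#' @param trace an `ei_trace`.
#' @param file path stem; `.tsv` and `.json` are appended.
#' @return `file`, invisibly.
#' @export
write_trace <- function(trace, file) {
  utils::write.table(as.data.frame(trace), paste0(file, ".tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- list(mode = trace$mode, a = trace$params$a,
                   b = trace$params$b, dt = trace$params$dt,
                   w0 = trace$params$basis$background,
                   input = trace$input, steady = isTRUE(trace$steady))
  jsonlite::write_json(manifest, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(file)
}
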