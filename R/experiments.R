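#' Stimulus ensembles
#'
#' Reproducible generators for the stimulus classes the preset experiments
#' use:
#' \describe{
#'   \item{`sparse`}{each input independently `amplitude` (default 100)
#'     with probability `p` (default 0.05), else 0.}
#'   \item{`grating`}{vertical square-wave grating on a 2-D input grid:
#'     bars `bar_width` pixels wide (default 8, period twice that),
#'     amplitude 20, phase uniform random per trial, orientation fixed.}
#'   \item{`context_blob`}{a single Gaussian blob (amplitude 100, width
#'     0.1 on the unit square) centred at `center`; constant across
#'     trials.}
#'   \item{`feature_combination`}{nonnegative feature coefficient vectors,
#'     uniform on `[0, amplitude]` per feature.}
#'   \item{`topographic_gaussian`}{1-D input profile
#'     `peak * exp(-|j - center| / 2)`; constant across trials.}
#' }
#'
#' @param kind ensemble kind, see Details.
#' @param n number of draws (columns).
#' @param m number of inputs (1-D kinds).
#' @param grid input grid `c(rows, cols)` (2-D kinds).
#' @param seed RNG seed; the same seed yields the identical ensemble.
#' @param p,amplitude,bar_width,center,width,peak,decay kind parameters.
#' @return an m x n matrix (inputs or coefficients per column).
#' @export
generate_ensemble <- function(kind = c("sparse", "grating", "context_blob",
                                       "feature_combination",
                                       "topographic_gaussian"),
                              n = 1L, m = NULL, grid = c(30L, 30L),
                              seed = NULL, p = 0.05, amplitude = NULL,
                              bar_width = 8L, center = NULL, width = 0.1,
                              peak = 150, decay = 2) {
  kind <- match.arg(kind)
  if (kind == "sparse") {
    amplitude <- amplitude %||% 100
    stopifnot(!is.null(m))
    return(with_seed(seed, matrix(
      amplitude * (stats::runif(m * n) < p), m, n)))
  }
  if (kind == "grating") {
    amplitude <- amplitude %||% 20
    rows <- grid[1]; cols <- grid[2]
    period <- 2L * bar_width
    with_seed(seed, {
      phases <- stats::runif(n, 0, period)
      vapply(phases, function(ph) {
        colval <- amplitude * (((seq_len(cols) - 1 + ph) %% period) <
                                 bar_width)
        as.numeric(matrix(rep(colval, each = rows), rows, cols))
      }, numeric(rows * cols))
    })
  } else if (kind == "context_blob") {
    amplitude <- amplitude %||% 100
    stopifnot(!is.null(center))
    rows <- grid[1]; cols <- grid[2]
    gx <- seq(0, 1, length.out = cols)
    gy <- seq(0, 1, length.out = rows)
    xy <- cbind(rep(gx, each = rows), rep(gy, times = cols))
    v <- amplitude * exp(-((xy[, 1] - center[1])^2 +
                             (xy[, 2] - center[2])^2) / (2 * width^2))
    matrix(v, nrow = rows * cols, ncol = n)
  } else if (kind == "feature_combination") {
    amplitude <- amplitude %||% 1
    stopifnot(!is.null(m))
    with_seed(seed, matrix(stats::runif(m * n, 0, amplitude), m, n))
  } else {
    stopifnot(!is.null(m))
    center <- center %||% ceiling(m / 2)
    v <- peak * exp(-abs(seq_len(m) - center) / decay)
    matrix(v, m, n)
  }
}

#' List the preset experiments
#'
#' @return character vector of experiment ids.
#' @export
list_experiments <- function() {
  c("fig2b", "fig2c", "fig2de", "fig3", "fig4", "fig5", "fig6d", "fig7",
    "fig8")
}

# shared: Poisson draws around a mean vector, columns = trials
pois_trials <- function(mu, trials) {
  matrix(stats::rpois(length(mu) * trials, rep(mu, trials)),
         nrow = length(mu))
}

se <- function(x) stats::sd(x) / sqrt(length(x))

#' Run a preset experiment
#'
#' Executes one of the package's figure protocols with its standard
#' parameters, all trial/presentation counts multiplied by `scale`. Every
#' preset is deterministic given `(id, seed, scale, model)`; if `out_dir`
#' is given, the result tables, a JSON manifest and a JSON metric report
#' are written there.
#'
#' @param id experiment id, see [list_experiments()].
#' @param seed integer RNG seed.
#' @param scale in (0, 1]: multiplies trial/presentation counts.
#' @param model `"divisive"`, `"subtractive"` or `"ln"` (the LN baseline is
#'   always fitted to the divisive model's responses on the same protocol).
#' @param out_dir optional output directory.
#' @return a list with elements `tables` (data frames), `metrics` (named
#'   scalars/vectors) and `manifest`.
#' @export
run_experiment <- function(id, seed = 1L, scale = 1,
                           model = c("divisive", "subtractive", "ln"),
                           out_dir = NULL) {
  model <- match.arg(model)
  if (!id %in% list_experiments())
    stop(sprintf("unknown experiment id '%s'", id), call. = FALSE)
  if (!is.numeric(scale) || scale <= 0 || scale > 1)
    stop("scale must be in (0, 1]", call. = FALSE)
  res <- switch(id,
    fig2b = exp_fig2b(seed, scale, model),
    fig2c = exp_fig2c(seed, scale, model),
    fig2de = exp_fig2de(seed, scale, model),
    fig3 = exp_fig3(seed, scale, model),
    fig4 = exp_fig4(seed, scale, model),
    fig5 = exp_fig5(seed, scale, model),
    fig6d = exp_fig6d(seed, scale, model),
    fig7 = exp_fig7(seed, scale, model),
    fig8 = exp_fig8(seed, scale, model))
  res$manifest <- c(list(id = id, seed = seed, scale = scale,
                         model = model,
                         package_version =
                           as.character(utils::packageVersion("divpred"))),
                    res$manifest)
  if (!is.null(out_dir)) write_experiment(res, out_dir)
  invisible(res)
}

write_experiment <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(res$tables))
    utils::write.table(res$tables[[nm]],
                       file.path(out_dir, paste0(nm, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(res$metrics, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

scaled_trials <- function(base, scale) {
  k <- as.integer(round(base * scale))
  if (k < 2L) stop("scale too small: fewer than 2 trials", call. = FALSE)
  k
}

# --- surround suppression: single stimulus +/- near or far context -------
exp_fig2b <- function(seed, scale, model) {
  n <- 30L
  k <- 15L
  trials <- scaled_trials(200L, scale)
  basis <- build_basis("paired", n_features = n, background = 0.01)
  # recorded neuron k integrates receptors k and k+1; the active stimulus
  # drives the shared receptor k+1, the context either k+2 (adjoint, near)
  # or k-1 (disjoint, far)
  mu_list <- list(none = {m <- rep(basis$background, n); m[k + 1] <- m[k + 1] + 50; m},
                  adjoint = {m <- rep(basis$background, n)
                             m[k + 1] <- m[k + 1] + 50; m[k + 2] <- m[k + 2] + 20; m},
                  disjoint = {m <- rep(basis$background, n)
                              m[k + 1] <- m[k + 1] + 50; m[k - 1] <- m[k - 1] + 20; m})
  set.seed(seed)
  draws <- lapply(mu_list, pois_trials, trials = trials)
  div <- divisive_model(basis)
  resp_div <- lapply(draws, function(S) div(S)[k, ])
  resp <- if (model == "divisive") {
    resp_div
  } else if (model == "subtractive") {
    # linear (unclamped) subtractive readout: suppression must not depend
    # on where the context falls relative to the RF
    sub <- subtractive_model(basis, clamp = FALSE)
    lapply(draws, function(S) sub(S)[k, ])
  } else {
    S_all <- do.call(cbind, draws)
    fit <- fit_ln(S_all, divisive_ml(basis, S_all))
    lapply(draws, function(S) ln_response(fit, S)[k, ])
  }
  tab <- data.frame(condition = rep(names(resp), each = trials),
                    trial = rep(seq_len(trials), 3),
                    response = unlist(resp, use.names = FALSE))
  means <- vapply(resp, mean, 0)
  ses <- vapply(resp, se, 0)
  metrics <- list(mean_none = means[["none"]],
                  mean_adjoint = means[["adjoint"]],
                  mean_disjoint = means[["disjoint"]],
                  se_none = ses[["none"]], se_adjoint = ses[["adjoint"]],
                  se_disjoint = ses[["disjoint"]],
                  ordering_ok = means[["none"]] > means[["disjoint"]] &&
                    means[["disjoint"]] > means[["adjoint"]],
                  adjoint_disjoint_rel_diff =
                    abs(means[["adjoint"]] - means[["disjoint"]]) /
                    mean(c(means[["adjoint"]], means[["disjoint"]])))
  list(tables = list(responses = tab), metrics = metrics,
       manifest = list(recorded_neuron = k, trials = trials, w0 = 0.01,
                       stimulus_means = list(none = 50,
                                             context = 20)))
}

# --- contextual shifts in tuning curves ----------------------------------
exp_fig2c <- function(seed, scale, model) {
  n <- 30L
  rec <- 15L
  trials <- scaled_trials(100L, scale)
  basis <- build_basis("circular", n_features = n, background = 0.01)
  masks <- list(none = NULL,
                right = list(receptor = rec + 3L, value = 200),
                left = list(receptor = rec - 3L, value = 200))
  div <- divisive_model(basis, engine = "dynamics", tol = 1e-6,
                        max_iter = 10000L)
  # paired conditions: one draw of the stimulus protocol, with every
  # receptor except the masked one identical across conditions (and the
  # LN baseline fitted to the divisive responses on these exact stimuli)
  mu <- basis$weights + basis$background
  set.seed(seed)
  S_base <- matrix(pois_trials(as.numeric(mu), trials), nrow = n)
  S_cond <- lapply(masks, function(mk) {
    S <- S_base
    if (!is.null(mk)) S[mk$receptor, ] <- mk$value
    S
  })
  stim_of_col <- rep(seq_len(n), times = trials)
  to_curves <- function(R) {
    M <- rowsum(t(as.matrix(R)), stim_of_col) / trials
    dimnames(M) <- NULL
    M
  }
  R_div <- lapply(S_cond, div)
  R_cond <- R_div
  if (model == "ln") {
    fit <- fit_ln(do.call(cbind, S_cond), do.call(cbind, R_div))
    R_cond <- lapply(S_cond, function(S) ln_response(fit, S))
  } else if (model == "subtractive") {
    sub <- subtractive_model(basis, clamp = FALSE)
    R_cond <- lapply(S_cond, sub)
  }
  curves <- lapply(R_cond, to_curves)
  sh <- context_shift_metrics(curves, circular = TRUE)
  # mask presented alone: should not drive the recorded neuron
  mask_alone <- {
    set.seed(seed + 2L)
    mu <- rep(basis$background, n)
    S <- pois_trials(mu, trials)
    S[masks$right$receptor, ] <- masks$right$value
    mean(div(S)[rec, ])
  }
  tab <- do.call(rbind, lapply(names(curves), function(nm)
    data.frame(context = nm, stimulus = seq_len(n),
               response = curves[[nm]][, rec])))
  metrics <- list(peak_shift_right_mask = sh$peak_shift[rec, 1],
                  peak_shift_left_mask = sh$peak_shift[rec, 2],
                  abs_shift = mean(abs(sh$peak_shift[rec, ])),
                  shift_away_ok = sh$peak_shift[rec, 1] < 0 &&
                    sh$peak_shift[rec, 2] > 0,
                  mask_alone_response = mask_alone)
  list(tables = list(tuning = tab), metrics = metrics,
       manifest = list(recorded_neuron = rec, trials = trials, w0 = 0.01,
                       mask_offset = 3, mask_value = 200))
}

# --- receptive-field reshaping by a grating context ----------------------
exp_fig2de <- function(seed, scale, model) {
  grid <- c(30L, 30L)
  basis <- build_basis("blob_grid", n_features = 400L, grid = grid,
                       background = 0.01)
  N <- scaled_trials(1e4L, scale)
  m <- prod(grid)
  # probe the neuron whose blob sits nearest the grid centre
  ctr <- which.min((basis$centers[, 1] - 0.5)^2 +
                     (basis$centers[, 2] - 0.5)^2)
  S_none <- generate_ensemble("sparse", n = N, m = m, seed = seed)
  S_grat <- generate_ensemble("sparse", n = N, m = m, seed = seed + 1L) +
    generate_ensemble("grating", n = N, grid = grid, seed = seed + 2L)
  div <- divisive_model(basis, tol = 1e-3, max_iter = 2000L)
  R_none <- div(S_none)
  R_grat <- div(S_grat)
  out <- list(
    rf_none = rf_from_data(S_none, R_none, neuron_ids = ctr,
                           context = "none"),
    rf_grating = rf_from_data(S_grat, R_grat, neuron_ids = ctr,
                              context = "grating"))
  if (model == "ln") {
    # LN fitted to the divisive responses over the pooled ensembles
    fit <- fit_ln(cbind(S_none, S_grat), cbind(R_none, R_grat))
    out$rf_none <- rf_from_data(S_none, ln_response(fit, S_none),
                                neuron_ids = ctr, context = "none")
    out$rf_grating <- rf_from_data(S_grat, ln_response(fit, S_grat),
                                   neuron_ids = ctr, context = "grating")
  }
  msd <- mean((scale_unit(out$rf_none$rf) - scale_unit(out$rf_grating$rf))^2)
  cs <- rf_center_surround(out$rf_none$rf[, 1], basis, ctr)
  tabs <- list(rf_none = as.data.frame(matrix(out$rf_none$rf, grid[1])),
               rf_grating = as.data.frame(matrix(out$rf_grating$rf, grid[1])))
  metrics <- list(rf_msd_between_contexts = msd,
                  center_value = cs$center,
                  surround_mean = cs$surround)
  list(tables = tabs, metrics = metrics,
       manifest = list(probed_neuron = ctr, presentations = N, w0 = 0.01,
                       grid = grid))
}

scale_unit <- function(v) {
  v <- as.numeric(v)
  s <- stats::sd(v)
  if (s < 1e-12) v * 0 else (v - mean(v)) / s
}

# centre pixel and surround-annulus mean (radii in unit-square units)
rf_center_surround <- function(rf, basis, neuron, r_in = 0.15, r_out = 0.3) {
  grid <- basis$input_geometry
  gx <- seq(0, 1, length.out = grid[2])
  gy <- seq(0, 1, length.out = grid[1])
  xy <- cbind(rep(gx, each = grid[1]), rep(gy, times = grid[2]))
  c0 <- basis$centers[neuron, ]
  d <- sqrt((xy[, 1] - c0[1])^2 + (xy[, 2] - c0[2])^2)
  list(center = rf[which.min(d)],
       surround = mean(rf[d >= r_in & d <= r_out]))
}

# --- multimodal ("olfactory") RF reshaping by a blob mask ---------------
exp_fig3 <- function(seed, scale, model) {
  grid <- c(30L, 30L)
  basis <- build_basis("multiblob", n_features = 400L, grid = grid,
                       background = 0.01, seed = seed)
  m <- prod(grid)
  N <- scaled_trials(1e4L, scale)
  probe <- c(1L, 2L, 3L)
  # mask: one blob at a fixed offset from the probed neuron's strongest blob
  strongest <- basis$centers[[probe[1]]][1, ]
  mask_center <- pmin(pmax(strongest + c(0.12, 0), 0), 1)
  mask <- generate_ensemble("context_blob", n = 1L, grid = grid,
                            center = mask_center)
  S_none <- generate_ensemble("sparse", n = N, m = m, seed = seed)
  S_mask <- generate_ensemble("sparse", n = N, m = m, seed = seed + 1L) +
    as.numeric(mask)
  mod <- switch(model,
                divisive = divisive_model(basis, tol = 1e-3,
                                          max_iter = 2000L),
                subtractive = subtractive_model(basis, tol = 1e-6,
                                                max_iter = 5000L),
                ln = NULL)
  if (is.null(mod)) {
    div <- divisive_model(basis, tol = 1e-3, max_iter = 2000L)
    mod <- fit_ln(cbind(S_none, S_mask),
                  cbind(div(S_none), div(S_mask)))
  }
  rf_none <- rf_from_data(S_none, eval_model(mod, S_none),
                          neuron_ids = probe, context = "none")
  rf_mask <- rf_from_data(S_mask, eval_model(mod, S_mask),
                          neuron_ids = probe, context = "mask")
  msd <- colMeans((apply(rf_none$rf, 2, scale_unit) -
                     apply(rf_mask$rf, 2, scale_unit))^2)
  tabs <- list(rf_none = as.data.frame(rf_none$rf),
               rf_mask = as.data.frame(rf_mask$rf))
  list(tables = tabs,
       metrics = list(rf_msd_per_neuron = as.numeric(msd)),
       manifest = list(probed_neurons = probe, presentations = N,
                       mask_center = mask_center, mask_amplitude = 100,
                       mask_width = 0.1, w0 = 0.01))
}

# --- invariant readout across mask contexts ------------------------------
exp_fig4 <- function(seed, scale, model) {
  n <- 30L
  # enough trials that readout-filter estimation noise sits well below the
  # cross-context invariance effect being measured
  trials <- scaled_trials(300L, scale)
  basis <- build_basis("circular", n_features = n, background = 0.01)
  set.seed(seed)
  mask_feats <- lapply(1:3, function(i) sample.int(n, 3L))
  masks <- lapply(mask_feats, function(f) 0.5 * rowSums(basis$weights[, f]))
  div <- divisive_model(basis, engine = "dynamics", tol = 1e-6,
                        max_iter = 10000L)
  gen_cond <- function(mask_vec, sd_offset) {
    set.seed(seed + sd_offset)
    mu <- basis$weights + basis$background + mask_vec
    S <- pois_trials(as.numeric(mu), trials)
    matrix(S, nrow = n)
  }
  S_ctx <- lapply(seq_along(masks), function(i) gen_cond(masks[[i]], i))
  R_div <- lapply(S_ctx, function(S) div(S))
  mod_is_ln <- model == "ln"
  R_ctx <- R_div
  if (mod_is_ln) {
    fit <- fit_ln(do.call(cbind, S_ctx), do.call(cbind, R_div))
    R_ctx <- lapply(S_ctx, function(S) ln_response(fit, S))
  } else if (model == "subtractive") {
    sub <- subtractive_model(basis, clamp = FALSE)
    R_ctx <- lapply(S_ctx, sub)
  }
  nv <- n
  stim_of_col <- rep(seq_len(nv), times = trials)
  curves <- lapply(R_ctx, function(R) {
    M <- rowsum(t(as.matrix(R)), stim_of_col) / trials
    dimnames(M) <- NULL
    M
  })
  readouts <- lapply(seq_along(S_ctx), function(i)
    fit_readout(S_ctx[[i]], R_ctx[[i]], context = paste0("mask", i)))
  errs <- vapply(seq_along(readouts), function(i)
    vapply(seq_along(S_ctx), function(j)
      reconstruction_error(readouts[[i]], S_ctx[[j]], R_ctx[[j]]), 0),
    numeric(length(S_ctx)))
  # errs[j, i]: decoder trained in context i, evaluated in context j
  matched <- mean(diag(errs))
  mismatched <- mean(errs[row(errs) != col(errs)])
  sh <- context_shift_metrics(curves, circular = TRUE)
  U_cols_cor <- vapply(seq_len(n), function(i) {
    cors <- utils::combn(3, 2, function(p)
      stats::cor(readouts[[p[1]]]$U[, i], readouts[[p[2]]]$U[, i]))
    mean(cors)
  }, 0)
  # similarity of the learned decoder to the generative weights
  U_vs_W_cor <- mean(vapply(seq_len(n), function(i)
    stats::cor(readouts[[1]]$U[, i], basis$weights[, i]), 0))
  err_tab <- data.frame(trained = rep(1:3, each = 3), evaluated = rep(1:3, 3),
                        error = as.numeric(errs))
  readout_sh <- context_shift_metrics(lapply(readouts, function(r) r$U))
  metrics <- list(matched_error = matched, mismatched_error = mismatched,
                  mismatch_ratio = mismatched / matched,
                  tuning_msd_mean = mean(sh$msd),
                  readout_msd_mean = mean(readout_sh$msd),
                  readout_col_cor_mean = mean(U_cols_cor),
                  readout_vs_generative_cor = U_vs_W_cor)
  list(tables = list(reconstruction_errors = err_tab),
       metrics = metrics,
       manifest = list(trials = trials, w0 = 0.01,
                       mask_features = mask_feats, mask_gain = 0.5))
}

# --- discriminating similar overlapping features -------------------------
exp_fig5 <- function(seed, scale, model) {
  grid <- c(30L, 30L)
  n <- 60L
  basis <- build_basis("multiblob", n_features = n, grid = grid,
                       background = 0.01, seed = seed)
  trials <- scaled_trials(20L, scale)
  # pick three mutually overlapping features
  O <- crossprod(basis$weights)
  diag(O) <- 0
  ij <- which(O == max(O), arr.ind = TRUE)[1, ]
  third <- which.max(pmin(O[, ij[1]], O[, ij[2]]))
  feats <- unique(c(ij[1], ij[2], third))[1:3]
  combos <- list(f1 = feats[1], f1_f2 = feats[1:2], f1_f3 = feats[c(1, 3)])
  set.seed(seed + 1L)
  div <- divisive_model(basis, tol = 1e-4, max_iter = 2000L)
  resp <- lapply(combos, function(f) {
    x <- numeric(n); x[f] <- 1
    S <- pois_trials(mean_input(basis, x), trials)
    rowMeans(div(S))
  })
  if (model == "ln") {
    set.seed(seed + 2L)
    Ntr <- scaled_trials(500L, scale)
    Xtr <- generate_ensemble("feature_combination", n = Ntr, m = n)
    Str <- matrix(stats::rpois(length(Xtr) / n * prod(grid),
                               as.numeric(mean_input_mat(basis, Xtr))),
                  nrow = prod(grid))
    fit <- fit_ln(Str, div(Str))
    resp <- lapply(combos, function(f) {
      x <- numeric(n); x[f] <- 1
      S <- pois_trials(mean_input(basis, x), trials)
      rowMeans(ln_response(fit, S))
    })
  }
  specificity <- vapply(seq_along(combos), function(i) {
    f <- combos[[i]]
    enc <- min(resp[[i]][f])
    non <- max(resp[[i]][-feats])
    enc / max(non, 1e-12)
  }, 0)
  tab <- data.frame(combo = rep(names(combos), each = n),
                    neuron = rep(seq_len(n), 3),
                    response = unlist(resp, use.names = FALSE))
  list(tables = list(responses = tab),
       metrics = list(specificity_ratio = specificity,
                      min_specificity = min(specificity),
                      encoding_features = feats),
       manifest = list(trials = trials, features = feats, w0 = 0.01))
}

# --- divisive gain control in the two-unit network -----------------------
exp_fig6d <- function(seed, scale, model) {
  w0 <- 1
  trials <- scaled_trials(100L, scale)
  I_test <- 10^seq(0, 3, length.out = 13)
  I_mask <- c(0, 50, 100, 200)
  set.seed(seed)
  resp <- sapply(I_mask, function(Im) {
    vapply(I_test, function(It) {
      s1 <- stats::rpois(trials, It)
      s2 <- stats::rpois(trials, Im)
      mean(steady_state_two_unit(s1, s2, w0))
    }, 0)
  })
  # input needed to reach half of the no-mask saturation level
  half <- 0.5 * max(resp[, 1])
  thresh <- vapply(seq_along(I_mask), function(k) {
    y <- resp[, k]
    i <- which(y >= half)[1]
    if (is.na(i)) return(NA_real_)
    if (i == 1L) return(I_test[1])
    # interpolate on log-input axis
    10^(log10(I_test[i - 1]) + (half - y[i - 1]) / (y[i] - y[i - 1]) *
          (log10(I_test[i]) - log10(I_test[i - 1])))
  }, 0)
  tab <- data.frame(I_test = rep(I_test, length(I_mask)),
                    I_mask = rep(I_mask, each = length(I_test)),
                    response = as.numeric(resp))
  list(tables = list(gain_curves = tab),
       metrics = list(half_max_threshold = thresh,
                      threshold_monotone = all(diff(thresh) > 0)),
       manifest = list(trials = trials, w0 = w0, I_mask = I_mask))
}

# --- temporal dynamics: contrast-dependent time to peak ------------------
exp_fig7 <- function(seed, scale, model) {
  basis <- feature_basis(matrix(c(40, 40), 2, 1), background = 1)
  params <- network_params(basis)
  amps <- c(50, 100, 150, 200)
  # the protocol is a divisive-vs-subtractive contrast; run both
  modes <- c("divisive", "subtractive")
  out <- list()
  for (md in modes) {
    tp <- vapply(amps, function(A) {
      tr <- simulate_network(params, c(A, 0), duration = 4,
                             record_every = 1e-3, mode = md)
      time_to_fraction(tr, unit = 1, fraction = 1, population = "exc")
    }, 0)
    out[[md]] <- tp
  }
  tr_ex <- simulate_network(params, c(100, 0), duration = 4,
                            record_every = 1e-3, mode = "divisive")
  peak_over_steady <- max(tr_ex$r_exc[, 1]) /
    tr_ex$r_exc[nrow(tr_ex$r_exc), 1]
  tab <- data.frame(mode = rep(names(out), each = length(amps)),
                    amplitude = rep(amps, length(out)),
                    time_to_peak = unlist(out, use.names = FALSE))
  metrics <- list(time_to_peak = out,
                  divisive_decreasing =
                    if (!is.null(out$divisive)) all(diff(out$divisive) < 0)
                    else NA,
                  subtractive_rel_range =
                    if (!is.null(out$subtractive))
                      diff(range(out$subtractive)) / mean(out$subtractive)
                    else NA,
                  peak_over_steady = peak_over_steady)
  list(tables = list(time_to_peak = tab), metrics = metrics,
       manifest = list(amplitudes = amps, a = params$a, b = params$b,
                       dt = params$dt, w0 = 1))
}

# --- traveling wave in the topographic network ---------------------------
exp_fig8 <- function(seed, scale, model) {
  m <- 30L
  k <- 15L
  basis <- build_basis("topographic_pair", n_features = m, background = 1)
  params <- network_params(basis)
  s <- as.numeric(generate_ensemble("topographic_gaussian", m = m,
                                    center = k))
  modes <- c("divisive", "subtractive")
  dist_max <- 8L
  units <- (k - dist_max):(k + dist_max)
  out <- list()
  traces <- list()
  for (md in modes) {
    tr <- simulate_network(params, s, duration = 4, record_every = 5e-4,
                           mode = md)
    lat <- vapply(units, function(u)
      time_to_fraction(tr, unit = u, fraction = 0.7, population = "exc"),
      0)
    out[[md]] <- data.frame(unit = units, distance = abs(units - k),
                            latency = lat)
    traces[[md]] <- tr
  }
  agg <- lapply(out, function(df)
    vapply(split(df$latency, df$distance), mean, 0))
  metrics <- list()
  if (!is.null(agg$divisive))
    metrics$divisive_latency_by_distance <- as.numeric(agg$divisive)
  if (!is.null(agg$subtractive)) {
    metrics$subtractive_latency_by_distance <- as.numeric(agg$subtractive)
    metrics$subtractive_rel_range <-
      diff(range(agg$subtractive)) / mean(agg$subtractive)
  }
  if (!is.null(agg$divisive))
    metrics$divisive_monotone <- all(diff(as.numeric(agg$divisive)) >= 0)
  tab <- do.call(rbind, lapply(names(out), function(md)
    cbind(mode = md, out[[md]])))
  list(tables = list(latency = tab), metrics = metrics,
       manifest = list(center = k, peak_input = 150, decay = 2,
                       distance_window = dist_max, a = params$a,
                       b = params$b, w0 = 1))
}
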