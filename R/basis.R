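#' Construct a feature basis (linear-Poisson generative model)
#'
#' A feature basis holds the nonnegative weight matrix `W` (m inputs x n
#' features) and the positive background rate `w0` of the generative model
#' in which feature intensities `x` drive sensory inputs with means
#' `W x + w0`. The same weights prescribe the connectivity of the
#' excitatory/inhibitory network realization: `W[j, i]` is both the drive of
#' feature `i` onto input `j` and the connection strength between excitatory
#' unit `j` and inhibitory unit `i`.
#'
#' @param weights numeric matrix, m x n, all entries finite and >= 0.
#' @param background positive scalar `w0`, the mean input rate when all
#'   features are zero.
#' @param input_geometry optional integer pair `c(rows, cols)` describing a
#'   2-D layout of the inputs; `rows * cols` must equal `nrow(weights)`.
#' @param feature_labels optional character vector of length n.
#' @param kind optional string recording how the basis was built.
#' @return an object of class `feature_basis`.
#' @seealso [build_basis()] for the standard constructions, [mean_input()],
#'   [sample_inputs()].
#' @export
feature_basis <- function(weights, background, input_geometry = NULL,
                          feature_labels = NULL, kind = NULL) {
  weights <- as.matrix(weights)
  check_nonneg_finite(weights, "weights")
  if (!is.numeric(background) || length(background) != 1L ||
      !is.finite(background) || background <= 0)
    stop("background (w0) must be a single positive number", call. = FALSE)
  if (!is.null(input_geometry)) {
    input_geometry <- as.integer(input_geometry)
    if (length(input_geometry) != 2L ||
        prod(input_geometry) != nrow(weights))
      stop("input_geometry rows*cols must equal the number of inputs",
           call. = FALSE)
  }
  if (!is.null(feature_labels) &&
      length(feature_labels) != ncol(weights))
    stop_dim("feature_labels", ncol(weights), length(feature_labels))
  structure(list(weights = weights, background = background,
                 input_geometry = input_geometry,
                 feature_labels = feature_labels, kind = kind),
            class = "feature_basis")
}

#' @export
print.feature_basis <- function(x, ...) {
  cat(sprintf("feature_basis: %d inputs x %d features, w0 = %g%s\n",
              nrow(x$weights), ncol(x$weights), x$background,
              if (is.null(x$kind)) "" else paste0(" (", x$kind, ")")))
  if (!is.null(x$input_geometry))
    cat(sprintf("  input grid: %d x %d\n",
                x$input_geometry[1], x$input_geometry[2]))
  invisible(x)
}

#' @export
dim.feature_basis <- function(x) dim(x$weights)

#' Mean input rates for a stimulus
#'
#' Evaluates the generative model: the expected activation of input `j`
#' given feature intensities `x` is `sum_k W[j,k] x[k] + w0`. Every
#' component is therefore at least `w0`.
#'
#' @param basis a [feature_basis()].
#' @param x numeric vector of n nonnegative feature intensities.
#' @return numeric vector of m mean input rates.
#' @export
mean_input <- function(basis, x) {
  stopifnot(inherits(basis, "feature_basis"))
  x <- as.numeric(x)
  if (length(x) != ncol(basis$weights))
    stop_dim("features", ncol(basis$weights), length(x))
  check_nonneg_finite(x, "stimulus x")
  drop(basis$weights %*% x) + basis$background
}

# matrix version used by the batched solvers: X is n x N
mean_input_mat <- function(basis, X) {
  basis$weights %*% X + basis$background
}

#' Sample noisy inputs from the generative model
#'
#' Draws input activations around the generative means. `"poisson"` gives
#' independent Poisson counts over a window of `window` seconds (the default
#' 1 s window makes counts equal to rates); `"gaussian"` adds constant-
#' variance normal noise, truncated at zero because inputs are nonnegative
#' activations.
#'
#' @param basis a [feature_basis()].
#' @param x feature intensity vector.
#' @param noise `"poisson"` or `"gaussian"`.
#' @param sigma standard deviation for Gaussian noise (default 1).
#' @param trials number of independent draws.
#' @param seed optional integer; with the same seed the draws are identical.
#' @param window observation window T in seconds (Poisson means are scaled
#'   by it and the returned counts divided back to rates).
#' @return if `trials == 1`, a numeric vector of m inputs; otherwise an
#'   m x trials matrix.
#' @export
sample_inputs <- function(basis, x, noise = c("poisson", "gaussian"),
                          sigma = 1, trials = 1L, seed = NULL, window = 1) {
  noise <- match.arg(noise)
  mu <- mean_input(basis, x)
  if (noise == "gaussian" && (!is.numeric(sigma) || sigma <= 0))
    stop("gaussian noise requires sigma > 0", call. = FALSE)
  if (window <= 0) stop("window must be positive", call. = FALSE)
  m <- length(mu)
  draws <- with_seed(seed, {
    if (noise == "poisson") {
      matrix(stats::rpois(m * trials, rep(mu * window, trials)) / window,
             nrow = m)
    } else {
      matrix(pmax(rep(mu, trials) +
                    stats::rnorm(m * trials, sd = sigma), 0), nrow = m)
    }
  })
  if (trials == 1L) drop(draws) else draws
}

#' Build one of the standard feature bases
#'
#' Constructs the weight matrices used throughout the package's simulated
#' preparations:
#' \describe{
#'   \item{`paired`}{each feature drives two neighbouring inputs with equal
#'     weight `w_max` (`W[i,i] = W[i+1,i] = w_max`, indices wrapping).}
#'   \item{`circular`}{ring of features on a 1-D stimulus axis (e.g.
#'     orientation/direction): `W[j,i] = w_max exp(4 [cos(2*pi/n (j-i)) - 1])`,
#'     a circulant, bell-shaped profile.}
#'   \item{`blob_grid`}{inputs on a `grid` (rows x cols) covering the unit
#'     square; feature `i` is a Gaussian blob of width `sigma_w` centred at
#'     `(x0_i, y0_i)`:
#'     `W[j,i] = w_max exp(-[(x_j-x0_i)^2+(y_j-y0_i)^2]/(2 sigma_w^2))`.
#'     Centres are a regular lattice when `n_features` is a perfect square,
#'     otherwise uniform random (seeded).}
#'   \item{`multiblob`}{distributed ("olfactory") selectivity: each feature
#'     is the sum of `n_blobs` Gaussian blobs with uniformly random centres.}
#'   \item{`letters`}{three features shaped like the letters V, I and A on a
#'     20 x 30 input grid, scaled to amplitude `w_max`; the bitmaps are
#'     synthetic package fixtures stored as plain-text rasters.}
#'   \item{`topographic_pair`}{same connectivity as `paired`, named for the
#'     topographic network in which inhibitory unit `i` drives excitatory
#'     units `i` and `i+1`.}
#' }
#'
#' @param kind one of `"paired"`, `"circular"`, `"blob_grid"`,
#'   `"multiblob"`, `"letters"`, `"topographic_pair"`.
#' @param n_features number of features n (fixed at 3 for `letters`).
#' @param m_inputs number of inputs m; defaults to `n_features` for the
#'   paired/circular kinds and to `prod(grid)` for the 2-D kinds.
#' @param w_max peak weight (default 40).
#' @param background background rate w0.
#' @param sigma_w blob width on the 0-1 grid (default 0.1).
#' @param grid integer pair, 2-D input layout for `blob_grid`/`multiblob`
#'   (default `c(30, 30)`).
#' @param n_blobs blobs per feature for `multiblob` (default 4).
#' @param centers optional n x 2 matrix of blob centres (blob_grid) or a
#'   list of per-feature `n_blobs` x 2 matrices (multiblob).
#' @param seed RNG seed for random centres.
#' @return a [feature_basis()].
#' @export
build_basis <- function(kind = c("paired", "circular", "blob_grid",
                                 "multiblob", "letters", "topographic_pair"),
                        n_features = 30L, m_inputs = NULL, w_max = 40,
                        background = 1, sigma_w = 0.1, grid = c(30L, 30L),
                        n_blobs = 4L, centers = NULL, seed = NULL) {
  kind <- match.arg(kind)
  if (w_max <= 0) stop("w_max must be positive", call. = FALSE)
  if (sigma_w <= 0) stop("sigma_w must be positive", call. = FALSE)
  n <- as.integer(n_features)

  if (kind %in% c("paired", "topographic_pair")) {
    m <- as.integer(m_inputs %||% n)
    W <- matrix(0, m, n)
    for (i in seq_len(n)) {
      W[((i - 1L) %% m) + 1L, i] <- w_max
      W[(i %% m) + 1L, i] <- w_max
    }
    return(feature_basis(W, background, kind = kind))
  }

  if (kind == "circular") {
    m <- as.integer(m_inputs %||% n)
    j <- seq_len(m); i <- seq_len(n)
    D <- outer(j, i, function(j, i) 2 * pi / n * (j - i))
    W <- w_max * exp(4 * (cos(D) - 1))
    return(feature_basis(W, background, kind = kind))
  }

  if (kind %in% c("blob_grid", "multiblob")) {
    grid <- as.integer(grid)
    m <- prod(grid)
    if (!is.null(m_inputs) && as.integer(m_inputs) != m)
      stop("m_inputs must equal prod(grid) for 2-D bases", call. = FALSE)
    gx <- seq(0, 1, length.out = grid[2])
    gy <- seq(0, 1, length.out = grid[1])
    # input j at (x, y): column-major over the rows-by-cols raster
    xy <- cbind(rep(gx, each = grid[1]), rep(gy, times = grid[2]))
    blob <- function(cx, cy)
      w_max * exp(-((xy[, 1] - cx)^2 + (xy[, 2] - cy)^2) / (2 * sigma_w^2))
    if (kind == "blob_grid") {
      if (is.null(centers)) {
        side <- sqrt(n)
        centers <- if (side == round(side)) {
          cs <- seq(0, 1, length.out = side)
          cbind(rep(cs, each = side), rep(cs, times = side))
        } else {
          with_seed(seed, cbind(stats::runif(n), stats::runif(n)))
        }
      }
      W <- vapply(seq_len(n), function(i) blob(centers[i, 1], centers[i, 2]),
                  numeric(m))
    } else {
      if (is.null(centers))
        centers <- with_seed(seed, lapply(seq_len(n), function(i)
          cbind(stats::runif(n_blobs), stats::runif(n_blobs))))
      W <- vapply(seq_len(n), function(i) {
        ci <- centers[[i]]
        rowSums(vapply(seq_len(nrow(ci)),
                       function(b) blob(ci[b, 1], ci[b, 2]), numeric(m)))
      }, numeric(m))
    }
    b <- feature_basis(W, background, input_geometry = grid, kind = kind)
    b$centers <- centers
    return(b)
  }

  # letters: fixed synthetic 20 x 30 rasters for V, I, A
  letters3 <- c("V", "I", "A")
  rasters <- lapply(letters3, read_letter_raster)
  # column-major flattening: matrix(W[, k], 20, 30) recovers the raster
  W <- w_max * vapply(rasters, function(r) as.numeric(r), numeric(600L))
  feature_basis(W, background, input_geometry = c(20L, 30L),
                feature_labels = letters3, kind = "letters")
}

# read a packaged 0/1 raster (rows of digits) as a rows x cols matrix
read_letter_raster <- function(letter) {
  f <- system.file("extdata",
                   sprintf("letter_%s_synthetic.txt", letter),
                   package = "divpred")
  if (!nzchar(f)) stop("letter raster fixture not found", call. = FALSE)
  lines <- readLines(f)
  do.call(rbind, lapply(strsplit(lines, ""), as.integer))
}

#' Write / read a feature basis as text
#'
#' The basis is serialized as a JSON header (background, kind, geometry,
#' labels) plus a tab-delimited weight matrix, both derived from `file` by
#' appending `.json` and `.tsv`.
#'
#' @param basis a [feature_basis()].
#' @param file path stem (no extension).
#' @return `write_basis` returns `file` invisibly; `read_basis` returns the
#'   reconstructed [feature_basis()].
#' @export
write_basis <- function(basis, file) {
  stopifnot(inherits(basis, "feature_basis"))
  header <- list(background = basis$background, kind = basis$kind,
                 input_geometry = basis$input_geometry,
                 feature_labels = basis$feature_labels,
                 m = nrow(basis$weights), n = ncol(basis$weights))
  jsonlite::write_json(header, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  utils::write.table(basis$weights, paste0(file, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname write_basis
#' @export
read_basis <- function(file) {
  header <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  W <- as.matrix(utils::read.table(paste0(file, ".tsv"), sep = "\t"))
  dimnames(W) <- NULL
  feature_basis(W, header$background,
                input_geometry = header$input_geometry,
                feature_labels = header$feature_labels, kind = header$kind)
}
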