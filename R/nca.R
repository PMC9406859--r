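# Min-max normalization, regularized neighborhood component analysis (NCA)
# feature weighting, and top-k index selection.
#
# NCA for feature selection learns one nonnegative weight per feature. Under
# the weighted L1 distance  d_w(x_i, x_j) = sum_l w_l^2 |x_il - x_jl|,
# point i picks a reference neighbour j with softmax probability
#   p_ij = exp(-d_w(x_i, x_j)/sigma) / sum_{k != i} exp(-d_w(x_i, x_k)/sigma)
# and the objective is the expected leave-one-out accuracy minus a ridge
# penalty:
#   F(w) = (1/n) sum_i p_i - lambda * sum_l w_l^2,
#   p_i  = sum_{j : y_j = y_i} p_ij .
# F is maximized by mini-batch gradient ascent from w = 1 with nonnegativity
# enforced by clipping; features that matter keep large weights, noise
# features are shrunk toward zero by the penalty.

#' NCA hyper-parameters
#'
#' @param lambda nonnegative ridge coefficient; `NULL` (default) means `1/n`,
#'   resolved when fitting.
#' @param sigma positive kernel width of the neighbour softmax (default 1),
#'   or `"auto"`: the mean pairwise weighted distance at the all-ones
#'   initialization, resolved by [fit_nca()]. With many features the raw
#'   distances are large and a unit width turns the softmax into a hard
#'   nearest-neighbour assignment with no usable gradient; `"auto"` keeps it
#'   responsive at any dimensionality.
#' @param learning_rate positive initial step size (default 0.1; decays as
#'   `learning_rate / epoch`).
#' @param max_epochs maximum passes over the data (default 100).
#' @param tolerance stop when the full-data objective improves by less than
#'   this between epochs (default 1e-6).
#' @param batch_size rows per mini-batch (default 32).
#' @param seed integer seed for the epoch shuffles (required).
#' @return A list of class `nca_params`.
#' @export
nca_params <- function(lambda = NULL, sigma = 1, learning_rate = 0.1,
                       max_epochs = 100L, tolerance = 1e-6, batch_size = 32L,
                       seed) {
  if (missing(seed)) stop("nca_params: `seed` is required")
  if (!is.null(lambda) && lambda < 0) stop("nca_params: `lambda` must be >= 0")
  if (!identical(sigma, "auto") && sigma <= 0) {
    stop("nca_params: `sigma` must be > 0 or \"auto\"")
  }
  if (learning_rate <= 0) stop("nca_params: `learning_rate` must be > 0")
  if (max_epochs < 1) stop("nca_params: `max_epochs` must be >= 1")
  if (tolerance <= 0) stop("nca_params: `tolerance` must be > 0")
  if (batch_size < 2) stop("nca_params: `batch_size` must be >= 2")
  structure(list(lambda = lambda, sigma = sigma, learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs), tolerance = tolerance,
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "nca_params")
}

#' Fit / apply per-feature min-max normalization
#'
#' `minmax_apply` maps each feature to `(x - min) / (max - min)` with the
#' extrema learned on the fit partition; constant features map to 0. Values
#' outside `[0, 1]` are possible (and allowed, not clipped) when the model is
#' applied to unseen data.
#'
#' @param X numeric matrix (rows = samples).
#' @return `minmax_fit`: a `minmax_model` with `min` and `max` vectors;
#'   `minmax_apply`: the normalized matrix.
#' @export
minmax_fit <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("minmax_fit: fit partition is empty")
  structure(list(min = apply(X, 2L, min), max = apply(X, 2L, max)),
            class = "minmax_model")
}

#' @rdname minmax_fit
#' @param model a `minmax_model`.
#' @export
minmax_apply <- function(model, X) {
  stopifnot(inherits(model, "minmax_model"))
  X <- as.matrix(X)
  if (ncol(X) != length(model$min)) {
    stop(sprintf("minmax_apply: model has %d features, matrix has %d",
                 length(model$min), ncol(X)))
  }
  range <- model$max - model$min
  scale <- ifelse(range > 0, 1 / range, 0)   # constant features -> 0
  sweep(sweep(X, 2L, model$min, "-"), 2L, scale, "*")
}

# Softmax-over-distances statistics and, optionally, the data term of the
# gradient, computed in row chunks so the |x_il - x_jl| pair matrix never
# exceeds ~max_cells elements. Returns mean(p_i) and the unweighted gradient
# accumulator  g_l = sum_i [ p_i sum_j p_ij M_ijl - sum_{j~i} p_ij M_ijl ].
.nca_core <- function(Xn, y, w, sigma, want_gradient = FALSE,
                      max_cells = 6e7) {
  n <- nrow(Xn); D <- ncol(Xn)
  w2 <- w^2
  chunk <- max(1L, min(n, as.integer(floor(max_cells / (as.double(n) * D)))))
  starts <- seq.int(1L, n, by = chunk)
  p_sum <- 0
  g <- if (want_gradient) numeric(D) else NULL
  for (s in starts) {
    I <- s:min(s + chunk - 1L, n)
    pi_idx <- rep(I, each = n)
    pj_idx <- rep.int(seq_len(n), length(I))
    M <- abs(Xn[pi_idx, , drop = FALSE] - Xn[pj_idx, , drop = FALSE])
    d <- matrix(M %*% w2, nrow = length(I), byrow = TRUE)   # |I| x n
    logK <- -d / sigma
    logK[cbind(seq_along(I), I)] <- -Inf                    # p_ii = 0
    a <- apply(logK, 1L, max)
    P <- exp(logK - a)
    P <- P / rowSums(P)
    same <- outer(y[I], y, "==")
    p_i <- rowSums(P * same)
    p_sum <- p_sum + sum(p_i)
    if (want_gradient) {
      cmat <- P * (p_i - same)          # c_ij = p_i p_ij - 1[y_i=y_j] p_ij
      g <- g + as.numeric(crossprod(M, as.numeric(t(cmat))))
    }
  }
  list(p_mean = p_sum / n, g = g)
}

# "auto" kernel width: mean pairwise weighted-L1 distance at w = 1, taken
# over a deterministic subsample of rows so the cost stays O(60^2 D).
.resolve_sigma <- function(sigma, Xn) {
  if (!identical(sigma, "auto")) return(sigma)
  n <- nrow(Xn)
  rows <- unique(round(seq(1L, n, length.out = min(n, 60L))))
  d <- as.matrix(stats::dist(Xn[rows, , drop = FALSE], method = "manhattan"))
  max(mean(d[upper.tri(d)]), .Machine$double.eps)
}

.check_nca_inputs <- function(Xn, y, w = NULL) {
  Xn <- as.matrix(Xn)
  if (nrow(Xn) < 2L) stop("nca: need at least 2 samples")
  if (!all(is.finite(Xn))) stop("nca: feature matrix must be finite")
  y <- factor(y)
  if (length(y) != nrow(Xn)) stop("nca: labels must align with rows")
  if (nlevels(droplevels(y)) < 2L) stop("nca: need at least 2 classes")
  if (!is.null(w) && length(w) != ncol(Xn)) {
    stop("nca: weight vector length must equal the number of features")
  }
  list(Xn = Xn, y = droplevels(y))
}

#' NCA objective value
#'
#' Regularized expected leave-one-out accuracy
#' `F(w) = mean_i(p_i) - lambda * sum(w^2)` under the softmax neighbour model
#' (see the package vignette). Stabilized by subtracting the row-wise maximum
#' of the scaled negative distances before exponentiation.
#'
#' @param Xn normalized feature matrix (rows = samples).
#' @param y class labels (>= 2 classes).
#' @param w nonnegative weight vector, one entry per feature.
#' @param params an [nca_params()] (only `lambda` and `sigma` are used;
#'   `lambda = NULL` resolves to `1/n`).
#' @return The scalar objective.
#' @export
nca_objective <- function(Xn, y, w, params) {
  inp <- .check_nca_inputs(Xn, y, w)
  if (identical(params$sigma, "auto")) {
    stop("nca_objective: sigma = \"auto\" is resolved by fit_nca(); pass a number")
  }
  lambda <- if (is.null(params$lambda)) 1 / nrow(inp$Xn) else params$lambda
  core <- .nca_core(inp$Xn, inp$y, w, params$sigma, want_gradient = FALSE)
  core$p_mean - lambda * sum(w^2)
}

#' NCA gradient
#'
#' Analytic gradient of [nca_objective()]:
#' `dF/dw_l = (2 w_l / sigma) * mean_i[ p_i sum_j p_ij |x_il - x_jl|`
#' `          - sum_{j: y_j = y_i} p_ij |x_il - x_jl| ] - 2 lambda w_l`.
#'
#' @inheritParams nca_objective
#' @return Numeric vector of length `ncol(Xn)`.
#' @export
nca_gradient <- function(Xn, y, w, params) {
  inp <- .check_nca_inputs(Xn, y, w)
  if (identical(params$sigma, "auto")) {
    stop("nca_gradient: sigma = \"auto\" is resolved by fit_nca(); pass a number")
  }
  n <- nrow(inp$Xn)
  lambda <- if (is.null(params$lambda)) 1 / n else params$lambda
  core <- .nca_core(inp$Xn, inp$y, w, params$sigma, want_gradient = TRUE)
  (2 * w / params$sigma) * (core$g / n) - 2 * lambda * w
}

#' Fit NCA feature weights by mini-batch gradient ascent
#'
#' Starts from `w = 1`, shuffles rows each epoch (seeded), ascends the
#' objective on batches of `batch_size` rows, and clips negative weights to
#' zero. The trace records the objective at initialization (exact) followed
#' by one stochastic estimate per epoch — the mean of the mini-batch
#' leave-one-out terms minus the penalty at the epoch's final weights — so
#' tracing adds no extra full passes over the data. Stops early when the
#' epoch-to-epoch improvement falls below `tolerance`.
#'
#' @inheritParams nca_objective
#' @param params an [nca_params()]; `sigma = "auto"` is resolved here (mean
#'   pairwise distance at initialization) and the resolved value is stored in
#'   the result.
#' @return Object of class `nca_weights`: `w` (nonnegative vector),
#'   `objective_trace` (element 1 = exact objective at initialization, then
#'   one estimate per epoch), `converged`, `lambda`, `params` (with `sigma`
#'   resolved).
#' @export
fit_nca <- function(Xn, y, params) {
  stopifnot(inherits(params, "nca_params"))
  inp <- .check_nca_inputs(Xn, y)
  Xn <- inp$Xn; y <- inp$y
  n <- nrow(Xn); D <- ncol(Xn)
  lambda <- if (is.null(params$lambda)) 1 / n else params$lambda
  sigma <- .resolve_sigma(params$sigma, Xn)
  pf <- nca_params(lambda = lambda, sigma = sigma,
                   learning_rate = params$learning_rate,
                   max_epochs = params$max_epochs, tolerance = params$tolerance,
                   batch_size = params$batch_size, seed = params$seed)
  w <- rep(1, D)
  trace <- nca_objective(Xn, y, w, pf)
  converged <- FALSE
  .with_preserved_rng(params$seed, {
    for (epoch in seq_len(params$max_epochs)) {
      lr <- params$learning_rate / epoch
      perm <- sample.int(n)
      batch_starts <- seq.int(1L, n, by = params$batch_size)
      p_terms <- numeric(0)
      for (s in batch_starts) {
        B <- perm[s:min(s + params$batch_size - 1L, n)]
        if (length(B) < 2L || nlevels(droplevels(y[B])) < 2L) next
        core <- .nca_core(Xn[B, , drop = FALSE], y[B], w, sigma,
                          want_gradient = TRUE)
        grad <- (2 * w / sigma) * (core$g / length(B)) - 2 * lambda * w
        w <- pmax(w + lr * grad, 0)
        p_terms <- c(p_terms, core$p_mean)
      }
      f <- if (length(p_terms) > 0L) mean(p_terms) - lambda * sum(w^2)
           else nca_objective(Xn, y, w, pf)
      if (!is.finite(f)) {
        stop(sprintf(paste0("fit_nca: non-finite objective at epoch %d; ",
                            "try a smaller learning_rate"), epoch))
      }
      trace <- c(trace, f)
      if (abs(f - trace[length(trace) - 1L]) < params$tolerance) {
        converged <- TRUE
        break
      }
    }
  })
  structure(list(w = w, objective_trace = trace, converged = converged,
                 lambda = lambda, params = pf),
            class = "nca_weights")
}

#' @export
print.nca_weights <- function(x, ...) {
  tr <- x$objective_trace
  cat(sprintf("<nca_weights> %d features, %d epochs, objective %.6f -> %.6f (%s)\n",
              length(x$w), length(tr) - 1L, tr[1L], tr[length(tr)],
              if (x$converged) "converged" else "max epochs"))
  invisible(x)
}

#' Select the top-k features by NCA weight
#'
#' @param weights an `nca_weights` object (or a bare numeric weight vector).
#' @param k number of features to keep (default 500).
#' @return Object of class `selection_result`: `indices` (1-based column
#'   indices ordered by descending weight, ties broken by ascending index),
#'   `k`, and `weights_at_selection`.
#' @export
select_top_k <- function(weights, k = 500L) {
  w <- if (inherits(weights, "nca_weights")) weights$w else as.numeric(weights)
  k <- as.integer(k)
  if (k < 1L || k > length(w)) {
    stop(sprintf("select_top_k: `k` must be in [1, %d], got %d", length(w), k))
  }
  ord <- order(-w, seq_along(w))
  idx <- ord[seq_len(k)]
  structure(list(indices = idx, k = k, weights_at_selection = w[idx]),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> top %d features; weight range [%.4g, %.4g]\n",
              x$k, min(x$weights_at_selection), max(x$weights_at_selection)))
  invisible(x)
}
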