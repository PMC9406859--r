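# Shared fixtures: tiny images, toy backends, and independent oracles.

# random 8-bit canvas image
random_canvas <- function(side = 256L, seed = 1L) {
  set.seed(seed)
  fundus_image(array(sample(0:255, side * side * 3, replace = TRUE),
                     dim = c(side, side, 3L)),
               source_id = sprintf("rand_%d", seed))
}

# toy linear backend with small dimensions for fast structural tests
toy_backend <- function(fc_dim = 4L, pool_dim = 6L, input_side = 8L, seed = 3L) {
  stub_backend(fc_dim = fc_dim, pool_dim = pool_dim,
               input_side = input_side, seed = seed)
}

# Independent brute-force oracle for the NCA objective and gradient:
# literal double loops over the defining formulas, no shared code with the
# implementation.
nca_brute_force <- function(X, y, w, lambda, sigma) {
  n <- nrow(X); D <- ncol(X)
  p_i <- numeric(n)
  grad_data <- numeric(D)
  for (i in seq_len(n)) {
    d <- vapply(seq_len(n),
                function(j) sum(w^2 * abs(X[i, ] - X[j, ])), numeric(1))
    e <- exp(-d / sigma)
    e[i] <- 0
    p <- e / sum(e)
    p_i[i] <- sum(p[y == y[i]])
    for (l in seq_len(D)) {
      Ml <- abs(X[i, l] - X[, l])
      grad_data[l] <- grad_data[l] +
        p_i[i] * sum(p * Ml) - sum((p * Ml)[y == y[i]])
    }
  }
  list(objective = mean(p_i) - lambda * sum(w^2),
       gradient = (2 * w / sigma) * (grad_data / n) - 2 * lambda * w)
}

# independently coded nearest-neighbour resize with the package's
# half-pixel-centre index mapping, written as direct per-pixel loops
nearest_resize_oracle <- function(px, out_rows, out_cols) {
  d <- dim(px)
  out <- array(0, dim = c(out_rows, out_cols, d[3L]))
  for (r in seq_len(out_rows)) {
    src_r <- (r - 0.5) * d[1L] / out_rows - 0.5
    ir <- min(max(floor(src_r + 0.5), 0), d[1L] - 1L) + 1L
    for (cc in seq_len(out_cols)) {
      src_c <- (cc - 0.5) * d[2L] / out_cols - 0.5
      ic <- min(max(floor(src_c + 0.5), 0), d[2L] - 1L) + 1L
      out[r, cc, ] <- px[ir, ic, ]
    }
  }
  out
}

# random confusion matrix with nonnegative integer entries, nonzero total
random_confusion <- function(C, max_count = 50L) {
  m <- matrix(sample(0:max_count, C * C, replace = TRUE), C, C)
  if (sum(m) == 0) m[1, 1] <- 1L
  m
}
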