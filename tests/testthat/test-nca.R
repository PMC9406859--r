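# Min-max normalization, the NCA objective/gradient against independent
# oracles, the mini-batch fit, and top-k selection.

test_that("min-max normalization follows the formula and its edge rules", {
  X <- cbind(a = c(0, 5, 10), b = c(3, 3, 3))
  mm <- minmax_fit(X)
  out <- minmax_apply(mm, X)
  expect_equal(out[, "a"], c(0, 0.5, 1))
  expect_equal(out[, "b"], c(0, 0, 0))          # constant features map to 0
  # hand evaluation on unseen data (no clipping outside [0,1])
  mm2 <- minmax_fit(rbind(c(0, 2), c(4, 6)))
  expect_equal(as.numeric(minmax_apply(mm2, rbind(c(2, 4)))), c(0.5, 0.5))
  expect_equal(as.numeric(minmax_apply(mm2, rbind(c(8, -2)))), c(2, -1))
  expect_error(minmax_apply(mm2, matrix(0, 1, 3)), "features")
  expect_error(minmax_fit(matrix(0, 0, 2)), "empty")
})

test_that("objective equals 1/3 by symmetry at w = 0 on balanced 4-point data", {
  set.seed(2)
  X <- matrix(rnorm(8), 4, 2)
  y <- c("a", "a", "b", "b")
  p0 <- nca_params(lambda = 0, sigma = 1, seed = 1)
  expect_equal(nca_objective(X, y, rep(0, 2), p0), 1 / 3)
  # penalty vanishes at w = 0 whatever lambda
  p1 <- nca_params(lambda = 5, sigma = 1, seed = 1)
  expect_equal(nca_objective(X, y, rep(0, 2), p1), 1 / 3)
  # gradient is identically zero at w = 0 (every term carries w_l)
  expect_equal(nca_gradient(X, y, rep(0, 2), p1), c(0, 0))
})

test_that("objective and gradient match the brute-force enumeration oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(4:10, 1); D <- sample(2:5, 1)
    X <- matrix(rnorm(n * D), n, D)
    y <- sample(rep(c("a", "b"), length.out = n))
    w <- runif(D, 0.1, 2)
    lambda <- runif(1, 0, 0.5); sigma <- runif(1, 0.5, 2)
    pp <- nca_params(lambda = lambda, sigma = sigma, seed = 1)
    oracle <- nca_brute_force(X, y, w, lambda, sigma)
    expect_equal(nca_objective(X, y, w, pp), oracle$objective, tolerance = 1e-10)
    expect_equal(nca_gradient(X, y, w, pp), oracle$gradient, tolerance = 1e-10)
  }
})

test_that("analytic gradient agrees with central finite differences", {
  set.seed(42)
  X <- matrix(rnorm(18), 6, 3)
  y <- rep(c("a", "b"), 3)
  w <- runif(3, 0.3, 1.5)
  pp <- nca_params(lambda = 0.2, sigma = 0.9, seed = 1)
  g <- nca_gradient(X, y, w, pp)
  h <- 1e-5
  fd <- vapply(1:3, function(l) {
    wp <- w; wm <- w
    wp[l] <- wp[l] + h; wm[l] <- wm[l] - h
    (nca_objective(X, y, wp, pp) - nca_objective(X, y, wm, pp)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(g - fd) / pmax(abs(fd), 1e-8)), 1e-4)
})

test_that("a large penalty dominates: gradient negative for all positive weights", {
  pm <- generate_planted_matrix(planted_matrix_spec(n = 40, D = 8,
                                                    n_informative = 3, seed = 3))
  w <- runif(8, 0.5, 1.5)
  pp <- nca_params(lambda = 1e3, sigma = 1, seed = 1)
  expect_true(all(nca_gradient(pm$X, pm$y, w, pp) < 0))
})

test_that("fitting upweights planted features and is seed-deterministic", {
  pm <- generate_planted_matrix(planted_matrix_spec(seed = 7))
  Xn <- minmax_apply(minmax_fit(pm$X), pm$X)
  nw <- fit_nca(Xn, pm$y, nca_params(seed = 7))
  noise <- setdiff(seq_len(50), pm$informative)
  expect_gt(mean(nw$w[pm$informative]), mean(nw$w[noise]))
  expect_true(all(nw$w >= 0))
  expect_true(all(is.finite(nw$objective_trace)))
  # ascent: final objective estimate at least the initial value
  tr <- nw$objective_trace
  expect_gte(tr[length(tr)], tr[1])
  # identical seed, identical weights bitwise
  nw2 <- fit_nca(Xn, pm$y, nca_params(seed = 7))
  expect_identical(nw$w, nw2$w)
})

test_that("label permutation destroys the signal and the penalty shrinks weights", {
  pm <- generate_planted_matrix(planted_matrix_spec(seed = 5))
  Xn <- minmax_apply(minmax_fit(pm$X), pm$X)
  set.seed(1)
  y_perm <- sample(pm$y)
  nw <- fit_nca(Xn, y_perm, nca_params(seed = 5))
  expect_lt(sum(nw$w^2), length(nw$w))          # below all-ones initialization
})

test_that("column permutation permutes the fitted weights identically", {
  pm <- generate_planted_matrix(planted_matrix_spec(n = 60, D = 12, seed = 9))
  Xn <- minmax_apply(minmax_fit(pm$X), pm$X)
  perm <- c(5, 1, 12, 3, 8, 2, 11, 4, 10, 6, 9, 7)
  nw_a <- fit_nca(Xn, pm$y, nca_params(seed = 4))
  nw_b <- fit_nca(Xn[, perm], pm$y, nca_params(seed = 4))
  expect_equal(nw_b$w, nw_a$w[perm], tolerance = 1e-12)
})

test_that("top-k selection orders by weight with index tie-breaks", {
  sel <- select_top_k(c(0.1, 0.9, 0.5), 2)
  expect_equal(sel$indices, c(2L, 3L))
  expect_equal(sel$weights_at_selection, c(0.9, 0.5))
  # all-equal weights: ascending index
  expect_equal(select_top_k(rep(1, 4), 3)$indices, 1:3)
  # k = D returns everything, ordered by weight
  sel_all <- select_top_k(c(0.3, 0.7, 0.1), 3)
  expect_equal(sel_all$indices, c(2L, 1L, 3L))
  expect_error(select_top_k(c(1, 2), 3), "\\[1, 2\\]")
  expect_error(select_top_k(c(1, 2), 0), "\\[1, 2\\]")
})

test_that("parameter validation rejects nonsense", {
  expect_error(nca_params(seed = 1, sigma = -1), "sigma")
  expect_error(nca_params(seed = 1, lambda = -0.1), "lambda")
  expect_error(nca_params(seed = 1, learning_rate = 0), "learning_rate")
  expect_error(nca_params(), "seed")
  expect_error(nca_objective(matrix(0, 1, 2), "a", c(1, 1),
                             nca_params(seed = 1)), "2 samples")
  X <- matrix(rnorm(8), 4, 2)
  expect_error(nca_objective(X, rep("a", 4), c(1, 1), nca_params(seed = 1)),
               "2 classes")
  # sigma = "auto" is a fit-time feature
  expect_error(nca_objective(X, c("a", "a", "b", "b"), c(1, 1),
                             nca_params(sigma = "auto", seed = 1)), "fit_nca")
})
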