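# Projection learning: Mahalanobis distances, objective, analytic gradient,
# the ascent contract and the relevance analysis.

test_that("squared Mahalanobis distances reduce to known special cases", {
  set.seed(21)
  X <- matrix(rnorm(12), 4, 3)
  expect_equal(sq_mahalanobis(X, diag(3)), as.matrix(stats::dist(X))^2,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(sq_mahalanobis(X, matrix(0, 2, 3)), matrix(0, 4, 4))

  X2 <- rbind(c(1, 0), c(0, 1))
  W <- rbind(c(2, 0), c(0, 1))
  expect_equal(sq_mahalanobis(X2, W)[1, 2], 5)  # ||(2,-1)||^2

  D2 <- sq_mahalanobis(X, matrix(rnorm(6), 2, 3))
  expect_equal(D2, t(D2))
  expect_equal(diag(D2), rep(0, 4))
  expect_true(all(D2 >= 0))
  expect_error(sq_mahalanobis(X, matrix(0, 2, 5)), "mismatch")
})

test_that("objective composes kernel, distance and alignment correctly", {
  # affine-in-B construction: K = e^-0.5 J + (1 - e^-0.5) B forces rho = 1
  X <- matrix(c(0, 0, 1), 3, 1)
  expect_equal(cka_objective(matrix(1, 1, 1), X, c(1, 1, 2)), 1.0,
               tolerance = 1e-10)

  set.seed(22)
  for (rep in 1:5) {
    Xr <- matrix(rnorm(24), 8, 3)
    tr <- sample(1:3, 8, replace = TRUE)
    if (length(unique(tr)) < 2) tr[1] <- tr[1] %% 3 + 1
    W <- matrix(rnorm(6, sd = 0.5), 2, 3)
    expect_equal(cka_objective(W, Xr, tr), cka_objective_oracle(W, Xr, tr),
                 tolerance = 1e-10)
  }

  expect_error(cka_objective(matrix(1, 1, 1), X, c(2, 2, 2)), "degenerate")
  # W = 0 collapses every sample: constant kernel
  expect_error(cka_objective(matrix(0, 1, 1), X, c(1, 1, 2)), "degenerate")
})

test_that("analytic gradient matches central finite differences", {
  set.seed(23)
  errs <- replicate(20, {
    N <- sample(6:10, 1); D <- sample(3:5, 1); m1 <- 2
    X <- matrix(rnorm(N * D), N, D)
    t <- sample(1:3, N, replace = TRUE)
    if (length(unique(t)) < 2) t[1] <- t[1] %% 3 + 1
    W <- matrix(rnorm(m1 * D, sd = 0.5), m1, D)
    fd <- finite_diff(function(w) cka_objective(w, X, t), W)
    grad_rel_error(cka_gradient(W, X, t), fd)
  })
  expect_lt(max(errs), 1e-5)
})

test_that("gradient is consistent under rescaling of the projection", {
  set.seed(24)
  X <- matrix(rnorm(40), 10, 4)
  t <- rep(1:2, 5)
  W <- matrix(rnorm(8, sd = 0.5), 2, 4)
  for (c_scale in c(0.5, 2)) {
    Wc <- c_scale * W
    fd <- finite_diff(function(w) cka_objective(w, X, t), Wc)
    expect_lt(grad_rel_error(cka_gradient(Wc, X, t), fd), 1e-5)
  }
})

test_that("gradient vanishes at the rho = 1 optimum", {
  X <- matrix(c(0, 0, 1), 3, 1)
  G <- cka_gradient(matrix(1, 1, 1), X, c(1, 1, 2))
  expect_lt(sqrt(sum(G^2)), 1e-6)
})

test_that("the ascent improves alignment and recovers the informative feature", {
  toy <- separable_toy(N = 60, D = 5, gap = 3, seed = 25)
  model <- fit_cka_projection(toy$X, toy$t, 2, optimizer_config(seed = 25))
  expect_gt(model$rho, model$trace$rho[1])
  expect_equal(which.max(model$relevance), 1L, ignore_attr = TRUE)
  # accepted-step trace never decreases
  expect_true(all(diff(model$trace$rho) >= 0))
  # trace rows are (iteration, rho) pairs starting at the initialization
  expect_equal(model$trace$iteration[1], 0L)
})

test_that("accepted-rho traces are non-decreasing on every seeded run", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(40 * 6), 40, 6)
    t <- sample(1:3, 40, replace = TRUE)
    X[, 2] <- X[, 2] + t
    m <- fit_cka_projection(X, t, 3,
                            optimizer_config(seed = seed, max_iter = 60))
    expect_true(all(diff(m$trace$rho) >= 0))
  }
})

test_that("fitting is deterministic and tol = Inf freezes the initialization", {
  toy <- separable_toy(seed = 26)
  m1 <- fit_cka_projection(toy$X, toy$t, 2, optimizer_config(seed = 7))
  m2 <- fit_cka_projection(toy$X, toy$t, 2, optimizer_config(seed = 7))
  expect_identical(m1$W, m2$W)

  # a huge tolerance stops after the first accepted step evaluation
  m0 <- fit_cka_projection(toy$X, toy$t, 2,
                           optimizer_config(tol = Inf, seed = 7))
  expect_lte(nrow(m0$trace), 2L)
})

test_that("dimension and sample-count constraints are enforced", {
  toy <- separable_toy(seed = 27)
  expect_error(fit_cka_projection(toy$X, toy$t, 6), "reduce dimension")
  expect_error(fit_cka_projection(toy$X[1:3, ], toy$t[1:3], 3), "overfit")
})

test_that("final alignment is scale-equivariant in data and initialization", {
  toy <- separable_toy(N = 30, D = 4, seed = 28)
  W0 <- matrix(rnorm(8, sd = 0.3), 2, 4)
  cfg <- optimizer_config(max_iter = 40, seed = 1)
  m_a <- fit_cka_projection(toy$X, toy$t, 2, cfg,
                            standardize = FALSE, init = W0)
  m_b <- fit_cka_projection(2 * toy$X, toy$t, 2, cfg,
                            standardize = FALSE, init = W0 / 2)
  expect_equal(m_a$rho, m_b$rho, tolerance = 1e-6)
})

test_that("relevance is the max-normalized mean squared column weight", {
  expect_equal(relevance(diag(4)), rep(1, 4), ignore_attr = TRUE)
  W <- rbind(c(2, 0), c(0, 1))
  expect_equal(relevance(W, normalize = FALSE), c(2, 0.5), ignore_attr = TRUE)
  expect_equal(relevance(W), c(1, 0.25), ignore_attr = TRUE)
  # invariant to row permutations
  expect_equal(relevance(W[2:1, ]), relevance(W))
  expect_warning(r0 <- relevance(matrix(0, 2, 3)), "all-zero")
  expect_equal(r0, rep(0, 3), ignore_attr = TRUE)
})

test_that("group relevance averages within feature families", {
  rel <- c(1, 0.5, 0.2, 0.4)
  g <- c("SV", "SV", "CV", "CV")
  expect_equal(as.vector(group_relevance(rel, g)), c(0.75, 0.3))
  expect_error(group_relevance(rel, g[1:2]), "length")
})

test_that("top-relevance ranking recovers planted informative features", {
  # 10 informative of 50 features at 1.5 sd separation; precision of the
  # top-10 ranking averaged over repeated draws
  n_seeds <- 20
  prec <- vapply(seq_len(n_seeds), function(seed) {
    spec <- synthetic_spec(group_sizes = c(CV = 25L, SV = 25L),
                           n_per_class = c(NC = 70L, MCI = 80L, AD = 60L),
                           informative_features = 26:35,
                           effect_size = 1.5, seed = seed)
    ds <- generate_synthetic(spec)
    m <- fit_cka_projection(ds$X, ds$t, 5,
                            optimizer_config(seed = seed, max_iter = 150))
    top <- order(m$relevance, decreasing = TRUE)[1:10]
    mean(top %in% 26:35)
  }, numeric(1))
  expect_gte(mean(prec), 0.8)
})
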