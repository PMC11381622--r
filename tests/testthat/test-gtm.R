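test_that("latent grid is a regular row-major lattice over [-1,1]^2", {
  g <- build_latent_grid(15)
  expect_equal(g$K, 225)
  expect_equal(nrow(g$nodes), 225)

  g2 <- build_latent_grid(2)
  expect_equal(unname(g2$nodes),
               cbind(c(-1, 1, -1, 1), c(1, 1, -1, -1)))  # row 1 on top
  g3 <- build_latent_grid(3)
  expect_true(any(g3$nodes[, 1] == 0 & g3$nodes[, 2] == 0))
  expect_error(build_latent_grid(1), ">= 2")
})

test_that("RBF basis matches the direct Gaussian formula cell by cell", {
  g <- build_latent_grid(15)
  b <- build_rbf_basis(g, 14)
  expect_equal(b$M, 196)
  expect_equal(ncol(b$Phi), 197)
  expect_true(all(b$Phi[, 197] == 1))

  g5 <- build_latent_grid(5)
  b5 <- build_rbf_basis(g5, 3, width_factor = 0.8)
  # independent formula evaluation
  for (l in seq_len(g5$K)) {
    for (j in seq_len(b5$M)) {
      d2 <- sum((g5$nodes[l, ] - b5$centres[j, ])^2)
      expect_equal(b5$Phi[l, j], exp(-d2 / (2 * b5$width^2)), tolerance = 1e-15)
    }
  }
  expect_true(all(b5$Phi[, 1:b5$M] > 0 & b5$Phi[, 1:b5$M] <= 1))
  # a node coinciding with a centre activates that RBF at exactly 1
  gc <- build_latent_grid(3)
  bc <- build_rbf_basis(gc, 3)
  for (l in 1:9) {
    j <- which(bc$centres[, 1] == gc$nodes[l, 1] &
                 bc$centres[, 2] == gc$nodes[l, 2])
    expect_equal(bc$Phi[l, j], 1)
  }
  expect_error(build_rbf_basis(g5, 3, width_factor = 0), "positive")
})

test_that("pca initialisation respects the principal plane and translation", {
  set.seed(5)
  # data exactly in a 2-D plane embedded in D=5
  basis_vecs <- qr.Q(qr(matrix(rnorm(10), 5, 2)))
  z <- matrix(rnorm(200), 100, 2) %*% diag(c(3, 1.5))
  x <- z %*% t(basis_vecs)
  g <- build_latent_grid(4)
  b <- build_rbf_basis(g, 2)
  m <- gtm_init(x, g, b, "pca")
  y <- reference_vectors(m)
  resid <- y - (sweep(y, 2, colMeans(x)) %*% basis_vecs) %*% t(basis_vecs) -
    rep(colMeans(x), each = nrow(y))
  expect_lt(max(abs(resid)), 1e-6)

  # translation equivariance of the initial reference vectors
  shift <- c(5, -3, 2, 0, 1)
  m2 <- gtm_init(sweep(x, 2, -shift), g, b, "pca")
  expect_equal(reference_vectors(m2), y + rep(shift, each = nrow(y)),
               tolerance = 1e-6)

  # rank-1 data cannot define a plane
  rank1 <- matrix(rnorm(50), 50, 1) %*% t(c(1, 2, 3))
  expect_error(gtm_init(rank1, g, b, "pca"), "random")

  # random init is seed-deterministic
  r1 <- gtm_init(x, g, b, "random", seed = 9)
  r2 <- gtm_init(x, g, b, "random", seed = 9)
  expect_identical(r1$W, r2$W)
})

test_that("e-step reproduces hand-computed responsibilities and likelihood", {
  # single component: responsibility 1 everywhere
  g1 <- phenomap:::single_node_grid()
  b1 <- phenomap:::bias_basis(g1)
  m1 <- phenomap:::new_gtm(g1, b1, W = matrix(0.3, 1, 1), beta = 2, lambda = 0,
                           seed = 0L)
  es1 <- gtm_e_step(m1, matrix(rnorm(5), 5, 1))
  expect_equal(as.numeric(es1$R), rep(1, 5))

  # D=1, K=2, centres (0,2), beta=1, x=0.5
  g2 <- build_latent_grid(2)
  grid2 <- list(side = 2L, K = 2L, nodes = matrix(c(-1, 1, 0, 0), 2, 2),
                row = c(1L, 1L), col = c(1L, 2L))
  class(grid2) <- "latent_grid"
  basis2 <- phenomap:::bias_basis(grid2)
  basis2$Phi <- diag(2)  # identity basis: W columns are the two centres
  m2 <- phenomap:::new_gtm(grid2, basis2, W = matrix(c(0, 2), 1, 2), beta = 1,
                           lambda = 0, seed = 0L)
  es2 <- gtm_e_step(m2, matrix(0.5))
  expect_equal(as.numeric(es2$R), c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))),
               tolerance = 1e-12)
  expect_equal(es2$log_likelihood, -1.4238, tolerance = 1e-4)
  # stabilised likelihood matches the naive direct evaluation
  y2 <- basis2$Phi %*% t(m2$W)
  expect_equal(es2$log_likelihood, naive_gtm_loglik(matrix(0.5), y2, 1),
               tolerance = 1e-6)

  expect_error(gtm_e_step(m2, matrix(NA_real_)), "complete")
})

test_that("e-step likelihood equals naive mixture evaluation on random instances", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(3:20, 1)
    d <- sample(2:4, 1)
    g <- build_latent_grid(sample(2:4, 1))  # K in {4, 9, 16}
    b <- build_rbf_basis(g, 2)
    m <- gtm_init(matrix(rnorm(n * d), n, d), g, b, "random", seed = seed)
    m$beta <- runif(1, 0.5, 3)
    x <- matrix(rnorm(n * d), n, d)
    es <- gtm_e_step(m, x)
    y <- reference_vectors(m)
    expect_equal(es$log_likelihood, naive_gtm_loglik(x, y, m$beta),
                 tolerance = 1e-6)
    expect_equal(unname(rowSums(es$R)), rep(1, n), tolerance = 1e-9)
    expect_true(all(es$R >= 0))
  }
})

test_that("m-step solves the penalised normal equations and shrinks with lambda", {
  set.seed(2)
  x <- matrix(rnorm(200), 50, 4)
  g <- build_latent_grid(3)
  b <- build_rbf_basis(g, 2)
  m <- gtm_init(x, g, b, "pca")
  es <- gtm_e_step(m, x)

  # one EM step never decreases the penalised objective
  obj_before <- phenomap:::gtm_penalised_objective(m, es$log_likelihood)
  m_new <- gtm_m_step(m, x, es$R)
  es_new <- gtm_e_step(m_new, x)
  obj_after <- phenomap:::gtm_penalised_objective(m_new, es_new$log_likelihood)
  expect_gte(obj_after, obj_before - 1e-8)

  # lambda -> infinity drives ||W|| (excluding bias) monotonically to 0
  norms <- vapply(c(1, 10, 1e3, 1e6), function(lam) {
    mm <- m
    mm$lambda <- lam
    up <- gtm_m_step(mm, x, es$R)
    sqrt(sum(up$W[, seq_len(b$M)]^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[4], 1e-3)

  # degenerate cluster: identical points, single bias-only component
  xc <- matrix(rep(c(1, -2), each = 20), 20, 2)
  g1 <- phenomap:::single_node_grid()
  b1 <- phenomap:::bias_basis(g1)
  m1 <- phenomap:::new_gtm(g1, b1, W = matrix(c(0, 0), 2, 1), beta = 1,
                           lambda = 0, seed = 0L)
  es1 <- gtm_e_step(m1, xc)
  up1 <- gtm_m_step(m1, xc, es1$R)
  expect_equal(as.numeric(up1$W), c(1, -2), tolerance = 1e-12)
  expect_equal(1 / up1$beta, 1e-8)  # variance floored, not divergent
})

test_that("EM objective ascends and the fit is seed-deterministic", {
  for (seed in 1:5) {
    set.seed(seed + 100)
    x <- scale(matrix(rnorm(80 * 4), 80, 4))
    m <- gtm_fit(x, side = 4, rbf_side = 2, lambda = 1, seed = seed,
                 max_iter = 60)
    expect_true(all(diff(m$trace$objective) > -1e-8))
  }
  x <- scale(matrix(rnorm(60 * 3), 60, 3))
  m1 <- gtm_fit(x, side = 4, rbf_side = 2, seed = 7)
  m2 <- gtm_fit(x, side = 4, rbf_side = 2, seed = 7)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$beta, m2$beta)
})

test_that("K=1 limit recovers the closed-form spherical Gaussian fit", {
  set.seed(21)
  x <- matrix(rnorm(200, sd = 2), 50, 4)
  m <- gtm_fit(x, side = 1, rbf_side = 0, lambda = 0, init = "random",
               seed = 1, max_iter = 50, tol = 1e-12)
  y <- reference_vectors(m)
  xbar <- colMeans(x)
  expect_equal(as.numeric(y), unname(xbar), tolerance = 1e-8)
  sigma2 <- sum(sweep(x, 2, xbar)^2) / (nrow(x) * ncol(x))
  expect_equal(1 / m$beta, sigma2, tolerance = 1e-8)
})

test_that("reference vectors equal Phi W' and degenerate to a constant map", {
  set.seed(4)
  x <- scale(matrix(rnorm(300), 75, 4))
  m <- gtm_fit(x, side = 4, rbf_side = 2, seed = 2, max_iter = 40)
  y <- reference_vectors(m)
  for (l in seq_len(m$grid$K)) {
    expect_equal(unname(y[l, ]), as.numeric(m$W %*% m$basis$Phi[l, ]))
  }
  # bias-only map: all reference vectors identical
  mb <- gtm_fit(x, side = 3, rbf_side = 0, lambda = 0, init = "random",
                seed = 1, max_iter = 20)
  yb <- reference_vectors(mb)
  expect_equal(max(apply(yb, 2, function(col) diff(range(col)))), 0)
})

test_that("micro-assignment takes the argmax with lowest-index ties", {
  set.seed(6)
  x <- scale(matrix(rnorm(240), 60, 4))
  m <- gtm_fit(x, side = 4, rbf_side = 2, seed = 3, max_iter = 40)
  y <- reference_vectors(m)
  # a subject sitting exactly on a reference vector is assigned to it
  far <- which.max(rowSums(sweep(y, 2, colMeans(y))^2))
  lab <- assign_micro(m, y[far, , drop = FALSE])
  expect_equal(lab, far)
  # argmax responsibility is the nearest reference vector (shared beta)
  labs <- assign_micro(m, x)
  d2 <- phenomap:::squared_distances(x, y)
  expect_equal(labs, apply(d2, 1, which.min))
  # exact tie breaks to the lower node index
  r <- matrix(c(0.2, 0.3, 0.3, 0.2), 1)
  expect_equal(max.col(r, ties.method = "first"), 2L)
})

test_that("model serialisation round-trips bit-exactly through JSON", {
  set.seed(8)
  x <- scale(matrix(rnorm(200), 50, 4))
  colnames(x) <- paste0("v", 1:4)
  scaler <- data.frame(variable = colnames(x), center = rnorm(4),
                       scale = runif(4, 0.5, 2))
  m <- gtm_fit(x, side = 4, rbf_side = 2, seed = 5, max_iter = 30,
               scaler = scaler)
  path <- tempfile(fileext = ".json")
  write_gtm(m, path)
  back <- read_gtm(path)
  expect_identical(unname(back$W), unname(m$W))
  expect_identical(back$beta, m$beta)
  expect_identical(back$lambda, m$lambda)
  expect_identical(back$basis$Phi, m$basis$Phi)
  expect_identical(back$var_names, colnames(x))
  expect_equal(back$scaler$center, scaler$center)
  # the reloaded model reproduces responsibilities exactly
  expect_identical(gtm_e_step(back, x)$R, gtm_e_step(m, x)$R)
})
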