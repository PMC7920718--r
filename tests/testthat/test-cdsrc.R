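test_that("cd_omp recovers an exact atom match in one iteration", {
  set.seed(1)
  D <- matrix(rnorm(8 * 5), 8, 5)
  D <- sweep(D, 2, sqrt(colSums(D^2)), "/")
  sol <- cd_omp(D[, 3], D, sparsity = 3)
  expect_equal(sol$support, 3L)
  expect_lt(sol$residual_norm, 1e-10)
})

test_that("cd_omp on an orthonormal dictionary picks atoms by coefficient size", {
  D <- diag(4)
  x <- 3 * D[, 1] + 1 * D[, 2]
  sol <- cd_omp(x, D, sparsity = 2)
  expect_equal(sol$support, c(1L, 2L))
  expect_equal(sol$coefficients, c(3, 1))
  expect_lt(sol$residual_norm, 1e-12)
})

test_that("cd_omp matches a from-scratch normal-equation OMP", {
  set.seed(20)
  for (rep in 1:30) {
    p <- sample(5:12, 1); m <- sample(4:10, 1)
    D <- matrix(rnorm(p * m), p, m)
    D <- sweep(D, 2, sqrt(colSums(D^2)), "/")
    x <- rnorm(p)
    k <- sample(1:min(m, p - 1), 1)
    mine <- cd_omp(x, D, k)
    orc <- oracle_omp(x, D, k)
    expect_equal(mine$support, orc$support)
    expect_equal(mine$residual_path, orc$residual_path, tolerance = 1e-10)
    # residual orthogonal to every selected atom
    expect_lt(max(abs(crossprod(D[, mine$support, drop = FALSE],
                                mine$residual))), 1e-8)
    # residual path non-increasing
    expect_true(all(diff(mine$residual_path) <= 1e-12))
  }
})

test_that("cd_omp with full support reaches the least-squares residual", {
  set.seed(4)
  D <- matrix(rnorm(10 * 6), 10, 6)
  D <- sweep(D, 2, sqrt(colSums(D^2)), "/")
  x <- rnorm(10)
  sol <- cd_omp(x, D, sparsity = 6)
  lsr <- sqrt(sum(stats::lsfit(D, x, intercept = FALSE)$residuals^2))
  expect_equal(sol$residual_norm, lsr, tolerance = 1e-10)
})

test_that("cd_knn_distance matches the brute-force oracle and toy cases", {
  expect_equal(cd_knn_distance(c(0, 0), cbind(c(0, 0), c(3, 4)), K = 1), 0)
  expect_equal(cd_knn_distance(c(0, 0), cbind(c(0, 0), c(3, 4)), K = 2), 2.5)
  set.seed(8)
  for (rep in 1:30) {
    p <- sample(2:6, 1); m <- sample(3:15, 1)
    M <- matrix(rnorm(p * m), p, m)
    x <- rnorm(p)
    K <- sample(1:(m + 2), 1)  # K may exceed the class size
    expect_equal(cd_knn_distance(x, M, K), oracle_knn_dist(x, M, K),
                 tolerance = 1e-12)
  }
})

test_that("cdsrc_fit normalizes columns, keeps duplicates, rejects small classes", {
  set.seed(12)
  X <- matrix(rnorm(24 * 4), 24, 4)
  X[13, ] <- X[14, ]  # duplicate training vector survives
  fs <- make_fset(X, rep(c("walk", "idle"), each = 12))
  m <- cdsrc_fit(fs, cdsrc_params(sparsity = 5, K = 3))
  for (d in m$dicts) {
    expect_equal(sqrt(colSums(d$normalized^2)), rep(1, ncol(d$normalized)),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_equal(ncol(m$dicts[["idle"]]$raw), 12)
  expect_error(cdsrc_fit(fs, cdsrc_params(sparsity = 15)), "at least 15")
})

test_that("lambda = 0 reduces classification to pure minimum residual", {
  set.seed(30)
  X <- rbind(matrix(rnorm(40 * 6, 1), 40, 6), matrix(rnorm(40 * 6, -1), 40, 6))
  y <- rep(c("a", "b"), each = 40)
  fs <- make_fset(X, y)
  m0 <- cdsrc_fit(fs, cdsrc_params(sparsity = 4, lambda = 0))
  Xte <- matrix(rnorm(10 * 6, 0.5), 10, 6)
  pred <- predict(m0, Xte)
  for (i in 1:10) {
    r <- vapply(m0$dicts, function(d)
      cd_omp(Xte[i, ], d$normalized, 4)$residual_norm, numeric(1))
    expect_equal(pred[i], names(which.min(r)), ignore_attr = TRUE)
  }
})

test_that("identical class dictionaries tie and resolve to the first class", {
  set.seed(31)
  X <- matrix(rnorm(20 * 5), 20, 5)
  fs <- make_fset(rbind(X, X), rep(c("a", "b"), each = 20))
  m <- cdsrc_fit(fs, cdsrc_params(sparsity = 3))
  pred <- predict(m, matrix(rnorm(5 * 5), 5, 5))
  expect_true(all(pred == "a"))
  sc <- attr(pred, "scores")
  expect_equal(sc[, 1], sc[, 2], tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("well-separated Gaussian classes are decoded at >= 0.95 accuracy", {
  set.seed(42)
  p <- 10
  mk <- function(mu, n) matrix(rnorm(n * p, mu, 1), n, p)
  tr <- make_fset(rbind(mk(2, 40), mk(-2, 40)),
                  rep(c("walk", "idle"), each = 40))
  te <- make_fset(rbind(mk(2, 20), mk(-2, 20)),
                  rep(c("walk", "idle"), each = 20))
  st <- standardize_features(tr, te, center = FALSE)
  m <- cdsrc_fit(st$train)
  expect_gte(mean(predict(m, st$test) == te$y), 0.95)
})

test_that("classification is invariant to global scaling of inputs", {
  set.seed(33)
  X <- rbind(matrix(rnorm(30 * 8, 0.5), 30, 8),
             matrix(rnorm(30 * 8, -0.5), 30, 8))
  y <- rep(c("a", "b"), each = 30)
  Xte <- matrix(rnorm(12 * 8), 12, 8)
  m1 <- cdsrc_fit(make_fset(X, y), cdsrc_params(sparsity = 5))
  m2 <- cdsrc_fit(make_fset(7.3 * X, y), cdsrc_params(sparsity = 5))
  expect_equal(as.character(predict(m1, Xte)),
               as.character(predict(m2, 7.3 * Xte)))
})

test_that("refitting on permuted rows yields identical predictions", {
  set.seed(34)
  X <- rbind(matrix(rnorm(30 * 6, 1), 30, 6), matrix(rnorm(30 * 6, -1), 30, 6))
  y <- rep(c("a", "b"), each = 30)
  perm <- sample(60)
  m1 <- cdsrc_fit(make_fset(X, y), cdsrc_params(sparsity = 5))
  m2 <- cdsrc_fit(make_fset(X[perm, ], y[perm]), cdsrc_params(sparsity = 5))
  Xte <- matrix(rnorm(8 * 6), 8, 6)
  expect_equal(as.character(predict(m1, Xte)),
               as.character(predict(m2, Xte)))
})

test_that("model save/load round trip preserves predictions", {
  set.seed(35)
  X <- rbind(matrix(rnorm(24 * 5, 1), 24, 5), matrix(rnorm(24 * 5, -1), 24, 5))
  y <- rep(c("a", "b"), each = 24)
  m <- cdsrc_fit(make_fset(X, y), cdsrc_params(sparsity = 4))
  f <- tempfile(fileext = ".json")
  cdsrc_save(m, f)
  m2 <- cdsrc_load(f)
  Xte <- matrix(rnorm(6 * 5), 6, 5)
  expect_equal(as.character(predict(m, Xte)), as.character(predict(m2, Xte)))
  expect_equal(m2$params$sparsity, 4)
  unlink(f)
})

test_that("dimension mismatches are rejected", {
  set.seed(36)
  X <- matrix(rnorm(40 * 5), 40, 5)
  m <- cdsrc_fit(make_fset(X, rep(c("a", "b"), 20)), cdsrc_params(sparsity = 4))
  expect_error(predict(m, matrix(0, 2, 4)), "dimension")
})
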