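test_that("initialization is seed-reproducible with uniform [-1,1] weights", {
  m1 <- elmInit(L = 23, d = 36, seed = 42)
  m2 <- elmInit(L = 23, d = 36, seed = 42)
  expect_identical(m1@a, m2@a)
  expect_identical(m1@b, m2@b)
  expect_equal(dim(m1@a), c(23L, 36L))
  expect_length(m1@b, 23)
  expect_true(all(m1@a >= -1 & m1@a <= 1))
  expect_true(all(m1@b >= -1 & m1@b <= 1))
})

test_that("hidden activations are sigmoid, with 0.5 at the hyperplane", {
  m <- elmInit(L = 2, d = 1, seed = 1)
  x0 <- -m@b[1] / m@a[1, 1]          # a x + b = 0 for node 1
  H <- elmHidden(m, matrix(x0, 1, 1))
  expect_equal(dim(H), c(1L, 2L))
  expect_equal(H[1, 1], 0.5)
  set.seed(2)
  X <- matrix(rnorm(15), 5, 3)
  m2 <- elmInit(L = 4, d = 3, seed = 2)
  H2 <- elmHidden(m2, X)
  expect_true(all(H2 > 0 & H2 < 1))
  # naive double-loop oracle
  O <- matrix(NA_real_, 5, 4)
  for (j in 1:5) for (l in 1:4)
    O[j, l] <- 1 / (1 + exp(-(sum(m2@a[l, ] * X[j, ]) + m2@b[l])))
  expect_equal(H2, O, tolerance = 1e-12)
  expect_error(elmHidden(m2, matrix(0, 2, 5)), "columns")
})

test_that("fitting solves H beta = Y exactly when H is square and invertible", {
  set.seed(3)
  n <- 6
  X <- matrix(rnorm(n * 2), n, 2)
  y <- rep(1:2, 3)
  m <- elmFit(elmInit(L = n, d = 2, seed = 3), X, y)
  H <- elmHidden(m, X)
  Y <- matrix(0, n, 2); Y[cbind(1:n, y)] <- 1
  expect_lt(max(abs(H %*% m@beta - Y)), 1e-8)
  expect_equal(predict(m, X), y)  # zero residual -> exact labels back
})

test_that("the residual is orthogonal to the column space of H", {
  for (s in 1:5) {
    set.seed(s)
    X <- matrix(rnorm(30 * 4), 30, 4)
    y <- sample(1:3, 30, replace = TRUE)
    m <- elmFit(elmInit(L = 10, d = 4), X, y)
    H <- elmHidden(m, X)
    Y <- matrix(0, 30, 3); Y[cbind(1:30, y)] <- 1
    R <- Y - H %*% m@beta
    expect_lte(norm(t(H) %*% R, "F"), 1e-6 * norm(t(H) %*% Y, "F"))
  }
})

test_that("beta matches the explicit normal-equations solution on a full-rank case", {
  set.seed(8)
  X <- matrix(rnorm(20 * 3), 20, 3)
  y <- sample(2:4, 20, replace = TRUE)
  m <- elmFit(elmInit(L = 5, d = 3, seed = 8), X, y)
  H <- elmHidden(m, X)
  Y <- matrix(0, 20, 3); Y[cbind(1:20, match(y, 2:4))] <- 1
  betaNE <- solve(t(H) %*% H, t(H) %*% Y)   # independent oracle
  expect_lt(max(abs(m@beta - betaNE)), 1e-6)
})

test_that("fitting requires at least two classes and a non-empty training set", {
  X <- matrix(rnorm(10), 5, 2)
  expect_error(elmFit(elmInit(L = 3, d = 2), X, rep(1, 5)), "2 classes")
  expect_error(elmFit(elmInit(L = 3, d = 2), X[0, , drop = FALSE],
                      integer(0)), "empty")
})

test_that("prediction decodes per-row argmax with ties toward the lower label", {
  m <- elmInit(L = 2, d = 1, seed = 5)
  m@classes <- c(3L, 7L)
  # craft beta so scores are [s1, s2] = H %*% beta with known ordering
  m@beta <- matrix(c(1, 1, 1, 1), 2, 2)   # both columns identical -> tie
  expect_equal(predict(m, matrix(c(-2, 0, 2), 3, 1)), rep(3L, 3))
  m@beta <- matrix(c(0, 0, 1, 1), 2, 2)   # column 2 dominates
  expect_equal(predict(m, matrix(0.5, 1, 1)), 7L)
  expect_error(predict(elmInit(L = 2, d = 1), matrix(0, 1, 1)), "fitted")
})

test_that("accuracy and Rho-squared follow their definitions", {
  truth <- c(rep(2L, 27), 3L)
  pred <- c(rep(2L, 27), 4L)
  pred[1] <- 2L
  expect_equal(classificationAccuracy(pred, truth), 27 / 28, tolerance = 1e-12)
  expect_equal(classificationAccuracy(1:5, 1:5), 1)
  expect_equal(rhoSquared(1:5, 1:5), 1)
  set.seed(10)
  a <- sample(2:24, 40, replace = TRUE)
  b <- sample(2:24, 40, replace = TRUE)
  covOracle <- (mean(a * b) - mean(a) * mean(b))^2 /
    ((mean(a^2) - mean(a)^2) * (mean(b^2) - mean(b)^2))
  expect_equal(rhoSquared(a, b), covOracle, tolerance = 1e-12)
  expect_equal(rhoSquared(rep(2, 10), 1:10), 0)
  expect_error(classificationAccuracy(1:3, 1:4), "length")
  expect_error(rhoSquared(1:3, 1:4), "length")
})

test_that("linearly separable two-class data reach perfect training accuracy when L >= N", {
  set.seed(12)
  X <- rbind(matrix(rnorm(20, -3, 0.3), 10, 2),
             matrix(rnorm(20, 3, 0.3), 10, 2))
  y <- rep(1:2, each = 10)
  m <- elmFit(elmInit(L = 20, d = 2, seed = 12), X, y)
  expect_equal(classificationAccuracy(predict(m, X), y), 1)
})

test_that("training accuracy does not degrade with more hidden nodes", {
  accAt <- function(L) {
    acc <- numeric(8)
    for (s in 1:8) {
      set.seed(s)
      X <- matrix(rnorm(40 * 3), 40, 3)
      y <- as.integer(X[, 1] + 0.5 * X[, 2] > 0) + 1L
      m <- elmFit(elmInit(L = L, d = 3, seed = s + 100), X, y)
      acc[s] <- classificationAccuracy(predict(m, X), y)
    }
    mean(acc)
  }
  expect_lte(accAt(2), accAt(8) + 1e-9)
  expect_lte(accAt(8), accAt(32) + 1e-9)
})

test_that("fitting is deterministic given fixed weights and data", {
  set.seed(14)
  X <- matrix(rnorm(24), 8, 3)
  y <- rep(1:2, 4)
  m0 <- elmInit(L = 4, d = 3, seed = 14)
  expect_identical(elmFit(m0, X, y)@beta, elmFit(m0, X, y)@beta)
})

test_that("a model survives a JSON round trip", {
  set.seed(15)
  X <- matrix(rnorm(20), 10, 2)
  y <- rep(2:3, 5)
  m <- elmFit(elmInit(L = 3, d = 2, seed = 15), X, y)
  path <- withr::local_tempfile(fileext = ".json")
  writeELM(m, path)
  m2 <- readELM(path)
  expect_equal(m2@a, m@a)
  expect_equal(m2@beta, m@beta)
  expect_equal(predict(m2, X), predict(m, X))
})
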