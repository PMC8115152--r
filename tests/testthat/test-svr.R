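test_that("RBF kernel evaluates as exp(-gamma d^2)", {
  x <- c(1.2, -0.4)
  expect_equal(rbf_kernel(x, x, 3), 1)
  expect_equal(rbf_kernel(c(1, 2), c(5, -1), 0), 1)
  expect_equal(rbf_kernel(c(2, 1), c(1, 1), 1.72), exp(-1.72))
  expect_equal(exp(-1.72), 0.17907, tolerance = 5e-5)
  expect_error(rbf_kernel(1, c(1, 2), 1))
})

test_that("constant responses give an empty expansion and exact bias", {
  set.seed(3)
  x <- matrix(rnorm(30), ncol = 2)
  m <- svr_fit(x, rep(2.5, 15), C = 1, gamma = 0.7, epsilon = 0.1)
  expect_true(all(m$beta == 0))
  expect_equal(m$b, 2.5)
  expect_equal(predict(m, x), rep(2.5, 15))
})

test_that("dual solution matches the brute-force QP oracle on random instances", {
  checked <- 0L
  for (seed in 1:30) {
    if (checked >= 20L) break
    set.seed(seed)
    n <- sample(6:25, 1)
    p <- sample(1:3, 1)
    x <- matrix(rnorm(n * p), ncol = p)
    y <- rowSums(x) + rnorm(n, 0, 0.3)
    C <- runif(1, 0.5, 20)
    gamma <- runif(1, 0.1, 3)
    epsilon <- runif(1, 0.01, 0.3)
    m <- svr_fit(x, y, C, gamma, epsilon)
    xs <- sweep(sweep(x, 2, m$center), 2, m$scale, "/")
    o <- oracle_svr_qp(xs, y, C, gamma, epsilon)
    if (is.null(o)) next  # oracle abstains on degenerate active sets
    checked <- checked + 1L
    expect_equal(m$dual_objective, o$objective, tolerance = 1e-6,
                 label = sprintf("objective seed %d", seed))
    pred_oracle <- drop(o$K %*% o$beta) + o$b
    expect_equal(unname(predict(m, x)), unname(pred_oracle),
                 tolerance = 1e-4, label = sprintf("predictions seed %d", seed))
    # box constraint holds exactly
    expect_true(all(abs(m$beta) <= C + 1e-12))
  }
  expect_gte(checked, 20L)
})

test_that("KKT conditions hold at the solution", {
  set.seed(21)
  x <- matrix(rnorm(60), ncol = 2)
  y <- x[, 1]^2 + rnorm(30, 0, 0.2)
  C <- 5; epsilon <- 0.1
  m <- svr_fit(x, y, C = C, gamma = 1, epsilon = epsilon)
  resid <- y - m$fitted
  for (i in seq_along(y)) {
    b <- m$beta[i]
    if (abs(b) < 1e-8) {
      expect_lte(abs(resid[i]), epsilon + 1e-3)     # inside the tube
    } else if (b > 1e-8 && b < C - 1e-8) {
      expect_equal(resid[i], epsilon, tolerance = 1e-3)
    } else if (b < -1e-8 && b > -C + 1e-8) {
      expect_equal(resid[i], -epsilon, tolerance = 1e-3)
    } else if (b >= C - 1e-8) {
      expect_gte(resid[i], epsilon - 1e-3)
    } else {
      expect_lte(resid[i], -epsilon + 1e-3)
    }
  }
  # points strictly inside the tube carry zero coefficient
  inside <- abs(resid) < epsilon - 1e-3
  expect_true(all(abs(m$beta[inside]) < 1e-6))
})

test_that("predictions agree with libsvm on identically scaled inputs", {
  set.seed(5)
  x <- matrix(runif(60), ncol = 2)
  y <- sin(3 * x[, 1]) + 2 * x[, 2] + rnorm(30, 0, 0.1)
  xs <- scale(x)
  m <- svr_fit(xs, y, C = 5, gamma = 1.5, epsilon = 0.1)
  ref <- e1071::svm(xs, y, type = "eps-regression", kernel = "radial",
                    cost = 5, gamma = 1.5, epsilon = 0.1, scale = FALSE)
  xq <- matrix(runif(20), ncol = 2)
  expect_equal(unname(predict(m, xq)), unname(predict(ref, xq)),
               tolerance = 5e-3)
})

test_that("widening the tube never adds support vectors", {
  set.seed(9)
  x <- matrix(rnorm(80), ncol = 2)
  y <- x[, 1] - 0.5 * x[, 2] + rnorm(40, 0, 0.3)
  n_sv <- vapply(c(0.01, 0.05, 0.1, 0.2, 0.5),
                 function(eps) length(svr_fit(x, y, C = 10, gamma = 0.5,
                                              epsilon = eps)$support),
                 numeric(1))
  expect_true(all(diff(n_sv) <= 0))
})

test_that("a single-support-vector expansion reduces to the kernel value", {
  m <- structure(list(beta = 1, b = 0, C = 1, gamma = 2, epsilon = 0.1,
                      x_train = matrix(c(0.3, -0.2), nrow = 1),
                      center = c(0, 0), scale = c(1, 1),
                      y_train = 1, fitted = 1, support = 1L,
                      dual_objective = NA, iterations = 0L,
                      converged = TRUE),
                 class = "svr_model")
  expect_equal(unname(predict(m, matrix(c(0.3, -0.2), nrow = 1))), 1)
})

test_that("serialized models round-trip through JSON", {
  set.seed(13)
  x <- matrix(rnorm(40), ncol = 2)
  y <- rowSums(x) + rnorm(20, 0, 0.1)
  m <- svr_fit(x, y, C = 3, gamma = 0.8, epsilon = 0.05)
  path <- tempfile(fileext = ".json")
  svr_to_json(m, path)
  m2 <- svr_from_json(path)
  xq <- matrix(rnorm(10), ncol = 2)
  expect_equal(predict(m2, xq), predict(m, xq), tolerance = 1e-12)
  expect_error(predict(m, matrix(1, 1, 3)), "3 feature")
})

test_that("degenerate inputs are rejected", {
  expect_error(svr_fit(matrix(c(1, NA), ncol = 1), c(1, 2), 1, 1), "finite")
  expect_error(svr_fit(matrix(1:4, ncol = 1), c(1, 2, Inf, 4), 1, 1),
               "finite")
})
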