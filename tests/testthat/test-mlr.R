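test_that("noise-free data generated by the full-set equation is recovered exactly", {
  ds <- generate_dataset(synth_config(noise_sd = 0, seed = 4))
  x <- as.data.frame(ds)[, c("cos2_alogp", "x3v", "neoplastic80")]
  fit <- suppressWarnings(ols_fit(x, ds$logkp))
  expect_equal(unname(coef(fit)),
               c(2.209, -6.698, -0.174, -0.704), tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
})

test_that("least squares and diagnostics match the normal-equations oracle", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(10:50, 1); p <- sample(1:5, 1)
    x <- matrix(rnorm(n * p), ncol = p)
    y <- rnorm(n)
    fit <- ols_fit(x, y)
    expect_equal(unname(coef(fit)), unname(oracle_ols(x, y)),
                 tolerance = 1e-8)
    # internal consistency of the fit statistics
    expect_equal(fit$F,
                 (fit$r2 / fit$p) / ((1 - fit$r2) / (fit$n - fit$p - 1)),
                 tolerance = 1e-8)
    expect_equal(fit$r2_adj,
                 1 - (1 - fit$r2) * (fit$n - 1) / (fit$n - fit$p - 1),
                 tolerance = 1e-10)
    expect_equal(fit$r2, cor(fit$fitted, y)^2, tolerance = 1e-10)
    if (p >= 2) expect_true(all(fit$coef_table$vif[-1] >= 1 - 1e-12))
  }
})

test_that("orthogonal centered descriptors have unit variance inflation", {
  # zero-mean mutually orthogonal (Hadamard-type) columns: all pairwise
  # correlations vanish, so each VIF must be exactly 1
  x <- cbind(a = rep(c(1, -1), 4),
             b = rep(c(1, 1, -1, -1), 2),
             c = rep(c(1, -1), each = 4))
  set.seed(1)
  fit <- ols_fit(x, rnorm(8))
  expect_equal(unname(fit$coef_table$vif[-1]), rep(1, 3), tolerance = 1e-10)
})

test_that("exact linear data gives a perfect fit", {
  x <- c(0, 1, 2)
  fit <- ols_fit(data.frame(x = x), 3 + 2 * x)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(unname(coef(fit)), c(3, 2), tolerance = 1e-10)
})

test_that("rank-deficient input raises an error naming collinear columns", {
  x <- data.frame(a = rnorm(20))
  x$b <- 2 * x$a
  expect_error(ols_fit(x, rnorm(20)), "collinear.*b")
})

test_that("stepwise selection keeps informative columns and guards collinearity", {
  set.seed(11)
  x <- data.frame(x1 = rnorm(80), x2 = rnorm(80))
  y <- 2 * x$x1 + rnorm(80, 0, 0.5)
  sel <- stepwise_select(x, y)
  expect_equal(sel$selected, "x1")
  # partial-F oracle: entry p of x1 equals its two-sided t-test p value
  f1 <- ols_fit(x["x1"], y)
  expect_lt(f1$coef_table$p[2], 0.05)

  x$x3 <- x$x1  # exact copy can never join x1
  sel2 <- stepwise_select(x, y)
  expect_false(all(c("x1", "x3") %in% sel2$selected))
})

test_that("null responses rarely admit any descriptor", {
  hits <- 0L
  for (seed in 1:40) {
    set.seed(seed + 500)
    x <- data.frame(a = rnorm(200), b = rnorm(200), c = rnorm(200))
    sel <- stepwise_select(x, rnorm(200))
    hits <- hits + (length(sel$selected) > 0L)
  }
  # P(at least one of three enters) is about 1 - 0.95^3 = 0.14
  expect_lt(hits / 40, 0.35)
  expect_gt(hits / 40, 0)  # but not structurally impossible
})

test_that("frozen published equations evaluate as printed", {
  zero <- data.frame(cos2_alogp = 0, x3v = 0, neoplastic80 = 0)
  expect_equal(predict_published("eq13", zero), 2.209)
  expect_equal(predict_published("eq10", zero), 0.624)
  expect_equal(predict_published("eq13",
                                 data.frame(cos2_alogp = 1, x3v = 0,
                                            neoplastic80 = 0)),
               2.209 - 6.698)
  expect_error(predict_published("eq99", zero), "unknown equation")
  expect_error(predict_published("eq13", data.frame(cos2_alogp = 1)),
               "x3v")
  # the printed full-set/training-set coefficient-order discrepancy is
  # preserved verbatim
  eqs <- published_equations()
  expect_equal(unname(eqs$eq13$coefficients["x3v"]), -0.174)
  expect_equal(unname(eqs$eq14$coefficients["x3v"]), -0.722)
})
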