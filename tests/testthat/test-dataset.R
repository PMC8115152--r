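make_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  path
}

test_that("compound tables read with validation and structured errors", {
  path <- make_csv(data.frame(id = c("a", "b", "c"),
                              smiles = c("CCO", "CCC", "c1ccccc1"),
                              logkp = c(-2.1, -1.5, -3.0)))
  ds <- read_qsar_table(path)
  expect_s3_class(ds, "qsar_dataset")
  expect_equal(nrow(ds), 3L)
  expect_equal(attr(ds, "descriptor_source"), "computed")
  expect_true(all(ds$split == "unassigned"))

  no_logkp <- make_csv(data.frame(id = "a", smiles = "CCO"))
  expect_error(read_qsar_table(no_logkp), "logkp")

  dup_id <- make_csv(data.frame(id = c("a", "a"), smiles = c("CCO", "CCC"),
                                logkp = c(-1, -2)))
  expect_error(read_qsar_table(dup_id), "duplicate id 'a' \\(row 2\\)")

  with_desc <- make_csv(data.frame(id = "a", smiles = "CCO", logkp = -1,
                                   cos2_alogp = 0.5, x3v = 0,
                                   neoplastic80 = 0))
  expect_equal(attr(read_qsar_table(with_desc), "descriptor_source"),
               "tabulated")
})

test_that("deduplication keeps one record per canonical structure and is idempotent", {
  ds <- qsar_dataset(data.frame(
    id = c("e1", "p1", "e2", "b1"),
    smiles = c("CCO", "CCC", "OCC", "c1ccccc1"),
    logkp = c(-2.10, -1.50, -2.105, -3.0)))
  out <- deduplicate(ds)
  expect_equal(nrow(out), 3L)
  expect_equal(out$id, c("e1", "p1", "b1"))     # first occurrence kept
  expect_equal(attr(out, "removed_ids"), "e2")
  expect_equal(as.data.frame(deduplicate(out)), as.data.frame(out),
               ignore_attr = TRUE)

  conflict <- qsar_dataset(data.frame(id = c("x", "y"),
                                      smiles = c("CCO", "OCC"),
                                      logkp = c(-2.0, -2.5)))
  expect_warning(deduplicate(conflict), "conflicting")

  disjoint <- qsar_dataset(data.frame(id = c("x", "y"),
                                      smiles = c("CCO", "CCC"),
                                      logkp = c(-2, -3)))
  expect_equal(nrow(deduplicate(disjoint)), 2L)
})

test_that("descriptor pre-filter drops constant and collinear columns", {
  set.seed(101)
  x <- cbind(a = rnorm(40), b = 1.5, c = rnorm(40))
  expect_equal(prefilter_descriptors(x), c(1L, 3L))

  x2 <- cbind(rnorm(40), rnorm(40))
  x2 <- cbind(x2, x2[, 1])
  expect_equal(prefilter_descriptors(x2), c(1L, 2L))

  x3 <- matrix(rnorm(50 * 5), ncol = 5)
  r <- cor(x3)
  expect_true(max(abs(r[upper.tri(r)])) < 0.9)  # oracle precondition
  expect_equal(prefilter_descriptors(x3), 1:5)
})

test_that("Kennard-Stone selection follows the max-min rule", {
  ks <- kennard_stone_split(matrix(c(0, 1, 2, 10), ncol = 1), 3)
  expect_equal(ks$selection_order, c(1L, 4L, 3L))
  expect_equal(ks$train, c(1L, 3L, 4L))
  expect_equal(ks$test, 2L)

  # n_train = n - 1 leaves out the point selected last by max-min
  set.seed(7)
  x <- matrix(rnorm(24), ncol = 2)
  ks2 <- kennard_stone_split(x, 11)
  expect_equal(ks2$test, setdiff(1:12, oracle_kennard_stone(x, 11)))
})

test_that("Kennard-Stone matches the brute-force oracle and is deterministic", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(10:50, 1)
    x <- matrix(rnorm(n * 3), ncol = 3)
    n_train <- sample(2:(n - 1), 1)
    ks <- kennard_stone_split(x, n_train)
    expect_equal(sort(ks$selection_order), sort(oracle_kennard_stone(x, n_train)))
    expect_identical(ks, kennard_stone_split(x, n_train))

    # coverage: every test point lies within the final max-min radius
    d <- as.matrix(dist(x))
    order_sel <- ks$selection_order
    radius <- min(d[order_sel[n_train], order_sel[-n_train]])
    for (t in ks$test) expect_lte(min(d[t, ks$train]), radius + 1e-12)
  }
})

test_that("degenerate all-identical rows split by lowest index", {
  x <- matrix(1, nrow = 5, ncol = 2)
  ks <- kennard_stone_split(x, 3)
  expect_equal(ks$selection_order, c(1L, 2L, 3L))
})

test_that("dataset-level split standardizes descriptors and yields the published sizes", {
  ds <- generate_dataset(synth_config(seed = 2))
  ds <- split_dataset(ds)
  expect_equal(sum(ds$split == "train"), 139L)
  expect_equal(sum(ds$split == "test"), 135L)
  ks <- attr(ds, "split_result")
  expect_equal(sort(c(ks$train, ks$test)), 1:274)
})
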