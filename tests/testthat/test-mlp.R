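toy_matrix <- function(x, y) {
  structure(list(x = x, y = y, dropped = character(0)), class = "ql_matrix")
}

test_that("split sizes follow largest-remainder rounding", {
  expect_equal(as.vector(table(split_dataset(23, seed = 1))), c(16, 4, 3))
  expect_equal(as.vector(table(split_dataset(100, seed = 1))), c(70, 15, 15))
  expect_equal(as.vector(table(split_dataset(7, seed = 1))), c(5, 1, 1))
  expect_identical(split_dataset(40, seed = 9), split_dataset(40, seed = 9))
  expect_false(identical(split_dataset(40, seed = 9), split_dataset(40, seed = 10)))
  expect_error(split_dataset(6), "at least 7")
})

test_that("a realizable linear map is fit essentially exactly", {
  set.seed(42)
  x <- matrix(rnorm(60), 60, 1, dimnames = list(NULL, "D1"))
  mat <- toy_matrix(x, 2 * x[, 1])
  sp <- split_dataset(60, seed = 3)
  # near-zero decay: the test probes the optimizer, not the regularizer
  net <- train_network(mat, sp, m = 1, seed = 5, decay = 1e-5)
  expect_gte(net$r_train, 0.999)
  expect_gte(net$r_combined, 0.999)
})

test_that("validation correlation under pure noise matches the Pearson null", {
  # Monte-Carlo null of |r| at the realized validation size (50 rows -> 7):
  # the trained network's validation correlation should clear the 0.5 mark
  # no less often than two independent vectors of that length do.
  set.seed(7)
  n_valid <- sum(split_dataset(50, seed = 1) == "validation")
  null_rate <- mean(replicate(4000, {
    abs(stats::cor(stats::rnorm(n_valid), stats::rnorm(n_valid))) < 0.5
  }))
  x <- matrix(rnorm(50 * 5), 50, 5, dimnames = list(NULL, paste0("D", 1:5)))
  hits <- 0L
  n_try <- 20L
  for (s in seq_len(n_try)) {
    y <- sample(rnorm(50))
    net <- train_network(toy_matrix(x, y), split_dataset(50, seed = s),
                         m = 2, seed = s)
    if (!is.na(net$r_valid) && abs(net$r_valid) < 0.5) hits <- hits + 1L
  }
  expect_gte(hits / n_try, null_rate - 0.2)
})

test_that("constant response is flagged as degenerate, not an error", {
  x <- matrix(rnorm(30), 30, 2, dimnames = list(NULL, c("D1", "D2")))
  net <- train_network(toy_matrix(x, rep(5, 30)), split_dataset(30, seed = 1),
                       m = 1, seed = 2)
  expect_true(net$degenerate)
  expect_true(is.na(net$r_train))   # r undefined, flagged via NA
})

test_that("package correlations equal the closed-form Pearson formula", {
  set.seed(1)
  a <- rnorm(40); b <- 0.3 * a + rnorm(40)
  closed <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(azolopharm:::safe_cor(a, b), closed, tolerance = 1e-12)
  expect_true(is.na(azolopharm:::safe_cor(a, rep(1, 40))))
})

test_that("column scaling is absorbed by standardization", {
  set.seed(11)
  x <- matrix(rnorm(50 * 3), 50, 3, dimnames = list(NULL, paste0("D", 1:3)))
  y <- x %*% c(1, -2, 0.5) + rnorm(50, 0, 0.1)
  sp <- split_dataset(50, seed = 4)
  net1 <- train_network(toy_matrix(x, as.numeric(y)), sp, m = 2, seed = 8)
  x2 <- x; x2[, 2] <- x2[, 2] * 4     # power of two: exact in floating point
  net2 <- train_network(toy_matrix(x2, as.numeric(y)), sp, m = 2, seed = 8)
  expect_equal(net1$r_train, net2$r_train, tolerance = 1e-10)
  expect_equal(net1$r_valid, net2$r_valid, tolerance = 1e-10)
})

test_that("prediction is deterministic given weights and inputs", {
  set.seed(2)
  x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("D1", "D2")))
  mat <- toy_matrix(x, x[, 1] - x[, 2])
  net <- train_network(mat, split_dataset(20, seed = 1), m = 2, seed = 3)
  p1 <- predict(net, x); p2 <- predict(net, x)
  expect_identical(p1, p2)
})
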