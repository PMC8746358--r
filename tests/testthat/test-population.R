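toy_matrix <- function(x, y) {
  structure(list(x = x, y = y, dropped = character(0)), class = "ql_matrix")
}

fake_net <- function(rt, rte, rv, seed = 1) {
  structure(list(r_train = rt, r_test = rte, r_valid = rv, seed = seed),
            class = "ql_network")
}

test_that("population on planted linear data keeps only strong fits", {
  set.seed(5)
  x <- matrix(rbinom(80 * 6, 3, 0.4), 80, 6, dimnames = list(NULL, paste0("D", 1:6)))
  y <- 3 * x[, 2] + rnorm(80, 0, 0.2)
  mat <- toy_matrix(x, y)
  sp <- split_dataset(80, seed = 2)
  pop <- train_population(mat, sp, n_total = 12, n_keep = 5, seed = 7)
  expect_length(pop, 5)
  expect_true(all(vapply(pop, function(n) n$r_train, 0) > 0.9))
})

test_that("single-network population returns that network", {
  set.seed(6)
  x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("D1", "D2")))
  mat <- toy_matrix(x, x[, 1])
  pop <- train_population(mat, split_dataset(20, seed = 1),
                          n_total = 1, n_keep = 1, seed = 3)
  expect_length(pop, 1)
  expect_error(train_population(mat, split_dataset(20, seed = 1),
                                n_total = 2, n_keep = 3), "n_keep")
})

test_that("a fixed master seed reproduces the kept population exactly", {
  set.seed(8)
  x <- matrix(rbinom(60 * 4, 3, 0.4), 60, 4, dimnames = list(NULL, paste0("D", 1:4)))
  mat <- toy_matrix(x, 2 * x[, 1] - x[, 3] + rnorm(60, 0, 0.3))
  sp <- split_dataset(60, seed = 5)
  p1 <- train_population(mat, sp, n_total = 8, n_keep = 3, seed = 21)
  p2 <- train_population(mat, sp, n_total = 8, n_keep = 3, seed = 21)
  expect_identical(lapply(p1, function(n) n$fit$wts),
                   lapply(p2, function(n) n$fit$wts))
  expect_identical(vapply(p1, function(n) n$seed, 0L),
                   vapply(p2, function(n) n$seed, 0L))
})

test_that("best-network selection follows the min/mean/order criterion", {
  a <- fake_net(0.9, 0.9, 0.9, seed = 1)
  b <- fake_net(0.99, 0.99, 0.2, seed = 2)
  expect_identical(select_best(list(a, b)), a)     # min criterion
  expect_identical(select_best(list(b)), b)        # singleton
  # exact tie on min and mean: earlier network wins
  c1 <- fake_net(0.8, 0.85, 0.9, seed = 10)
  c2 <- fake_net(0.9, 0.85, 0.8, seed = 11)
  expect_identical(select_best(list(c1, c2)), c1)
  expect_error(select_best(list()), "empty")
})

test_that("sensitivity is exactly 1 for an input the network ignores", {
  set.seed(9)
  x <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("D1", "D2")))
  mat <- toy_matrix(x, x[, 1] * 2)
  sp <- split_dataset(30, seed = 4)
  net <- train_network(mat, sp, m = 1, seed = 6)
  # surgically cut all outgoing weights of input 2: nnet stores
  # input->hidden weights per hidden unit in blocks (bias, in1, in2, ...)
  nw <- net
  wmat <- matrix(nw$fit$wts[seq_len((2 + 1) * 1)], ncol = 1)
  wmat[3, 1] <- 0
  nw$fit$wts[seq_len(3)] <- as.numeric(wmat)
  s <- sensitivity(nw, mat, sp)
  expect_identical(s$sens[s$label == "D2"], 1)
})

test_that("the sole informative input of a clean fit dominates sensitivity", {
  set.seed(10)
  x <- matrix(rbinom(100 * 3, 3, 0.5), 100, 3, dimnames = list(NULL, paste0("D", 1:3)))
  mat <- toy_matrix(x, 5 * x[, 1])
  sp <- split_dataset(100, seed = 2)
  net <- train_network(mat, sp, m = 2, seed = 4)
  s <- sensitivity(net, mat, sp)
  expect_equal(s$label[1], "D1")
  expect_gt(s$sens[1], 10)
})

test_that("a perfectly collinear duplicate dilutes per-column sensitivity", {
  set.seed(12)
  base <- matrix(rbinom(300, 3, 0.5), 100, 3, dimnames = list(NULL, paste0("D", 1:3)))
  y <- 4 * base[, 1] + rnorm(100, 0, 0.1)
  sp <- split_dataset(100, seed = 3)
  net_u <- train_network(toy_matrix(base, y), sp, m = 2, seed = 5)
  s_u <- sensitivity(net_u, toy_matrix(base, y), sp)
  dup <- cbind(base, D1b = base[, 1])
  net_d <- train_network(toy_matrix(dup, y), sp, m = 2, seed = 5)
  s_d <- sensitivity(net_d, toy_matrix(dup, y), sp)
  sens_unique <- s_u$sens[s_u$label == "D1"]
  expect_lte(s_d$sens[s_d$label == "D1"], sens_unique)
  expect_lte(s_d$sens[s_d$label == "D1b"], sens_unique)
})
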