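toy_matrix <- function(x, y) {
  structure(list(x = x, y = y, dropped = character(0)), class = "ql_matrix")
}

small_ctrl <- function(...) qlnet_control(n_total = 12L, n_keep = 4L, ...)

test_that("an exact single-column signal survives pruning with near-perfect fit", {
  set.seed(3)
  x <- matrix(rbinom(60 * 5, 3, 0.4), 60, 5, dimnames = list(NULL, paste0("D", 1:5)))
  fit <- qlnet(toy_matrix(x, 3 * x[, 2]),
               control = small_ctrl(decay = 1e-5), seed = 2)
  expect_true("D2" %in% colnames(fit$matrix$x))
  expect_gte(utils::tail(fit$iterations$r_combined, 1), 0.999)
  expect_equal(fit$pharmacophore$descriptors$label[1], "D2")
})

test_that("the loop terminates in at most k iterations with decreasing width", {
  set.seed(4)
  x <- matrix(rbinom(50 * 8, 3, 0.4), 50, 8, dimnames = list(NULL, paste0("D", 1:8)))
  y <- 2 * x[, 1] - 3 * x[, 5] + rnorm(50, 0, 0.5)
  fit <- qlnet(toy_matrix(x, y), control = small_ctrl(), seed = 6)
  expect_lte(nrow(fit$iterations), 8)
  k_seq <- fit$iterations$k
  expect_true(all(diff(k_seq) < 0) || nrow(fit$iterations) == 1)
  expect_equal(utils::tail(fit$iterations$n_pruned, 1) == 0 ||
               nrow(fit$iterations) == fit$control$max_iter, TRUE)
})

test_that("reruns from one master seed are bit-identical", {
  set.seed(5)
  x <- matrix(rbinom(40 * 6, 3, 0.4), 40, 6, dimnames = list(NULL, paste0("D", 1:6)))
  y <- 2 * x[, 3] + rnorm(40, 0, 0.4)
  f1 <- qlnet(toy_matrix(x, y), control = small_ctrl(), seed = 31)
  f2 <- qlnet(toy_matrix(x, y), control = small_ctrl(), seed = 31)
  expect_identical(f1$iterations, f2$iterations)
  expect_identical(f1$network$fit$wts, f2$network$fit$wts)
  expect_identical(f1$pharmacophore$descriptors, f2$pharmacophore$descriptors)
  expect_identical(coef(f1), coef(f2))
})

test_that("pruning everything raises an error carrying the last report", {
  set.seed(7)
  x <- matrix(rbinom(40 * 3, 3, 0.4), 40, 3, dimnames = list(NULL, paste0("D", 1:3)))
  y <- x[, 1] + rnorm(40, 0, 0.2)
  err <- tryCatch(
    qlnet(toy_matrix(x, y),
          control = small_ctrl(prune_threshold = 50, sens_threshold = 50),
          seed = 1),
    error = function(e) e)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "all descriptor columns pruned")
  expect_s3_class(err$sens_report, "sens_report")
})

test_that("pharmacophore extraction applies the threshold filter", {
  rep_df <- data.frame(label = c("d1", "d2", "d3"), sens = c(1.27, 1.22, 1.05))
  class(rep_df) <- c("sens_report", "data.frame")
  ph <- extract_pharmacophore(rep_df, threshold = 1.1)
  expect_equal(ph$descriptors$label, c("d1", "d2"))
  ph_all <- extract_pharmacophore(rep_df, threshold = 1.0)
  expect_equal(nrow(ph_all$descriptors), 3)
  expect_warning(extract_pharmacophore(rep_df, threshold = 2), "no descriptor")
})

test_that("qlnet methods cohere (predict, fitted, residuals, coef)", {
  set.seed(8)
  x <- matrix(rbinom(40 * 4, 3, 0.4), 40, 4, dimnames = list(NULL, paste0("D", 1:4)))
  y <- 2 * x[, 1] + rnorm(40, 0, 0.3)
  fit <- qlnet(toy_matrix(x, y), control = small_ctrl(), seed = 9)
  expect_equal(unname(fitted(fit)), predict(fit, x))
  expect_equal(unname(residuals(fit)), y - predict(fit, x))
  expect_named(coef(fit))
  # predicting from data missing pruned columns pads with zero counts
  p <- predict(fit, x[, 1, drop = FALSE])
  expect_length(p, 40)
  # serialization round trip preserves weights
  tmp <- tempfile(fileext = ".json")
  write_network_json(fit$network, tmp)
  obj <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(obj$wts, fit$network$fit$wts)
  expect_equal(obj$k, fit$network$k)
})

test_that("control invariants are enforced", {
  expect_error(qlnet_control(sens_threshold = 0.9), "sens_threshold")
  expect_error(qlnet_control(max_iter = 0), "max_iter")
})
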