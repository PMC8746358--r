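#' Split compounds into training / test / validation sets
#'
#' Uniformly random assignment at the given ratios (default 70/15/15),
#' reproducible from the seed.  Partition sizes follow the largest-remainder
#' rounding rule; remainder ties go to the earlier partition.
#'
#' @param n number of rows, or a \code{ql_matrix} whose row count is used.
#' @param ratios length-3 numeric vector summing to 1.
#' @param seed integer seed.
#' @return a factor of length \code{n} with levels
#'   \code{train}, \code{test}, \code{validation}.
#' @examples
#' table(split_dataset(23, seed = 1))  # 16 / 4 / 3
#' @export
split_dataset <- function(n, ratios = c(0.70, 0.15, 0.15), seed = 1L) {
  if (inherits(n, "ql_matrix")) n <- nrow(n$x)
  n <- as.integer(n)
  if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-8)
    stop("'ratios' must be three fractions summing to 1")
  if (n < 7L) stop("need at least 7 rows so that all partitions are non-empty")
  raw <- n * ratios
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    frac <- raw - sizes
    extra <- order(-frac)[seq_len(rem)]   # stable: ties to earlier partition
    sizes[extra] <- sizes[extra] + 1L
  }
  if (any(sizes == 0L)) stop("a partition would be empty at these ratios")
  lev <- c("train", "test", "validation")
  set.seed(seed)
  assign <- sample(rep(lev, times = sizes))
  factor(assign, levels = lev)
}

#' Train one narrow-throat MLP regressor (k-m-1)
#'
#' Fits a single-hidden-layer perceptron with \code{m} logistic hidden units
#' and a linear output on the training partition, with early stopping on the
#' test partition: the optimizer (BFGS batch training via [nnet::nnet()]) is
#' run in segments, warm-restarted from the previous weights, and the weights
#' with the lowest test-partition error are kept.  Inputs and the response
#' are standardized by training-partition statistics.
#'
#' @param matrix a \code{ql_matrix} (see [build_descriptor_matrix()]) or a
#'   list with numeric matrix \code{x} and response \code{y}.
#' @param split partition factor from [split_dataset()].
#' @param m number of hidden neurons (must satisfy \code{m < k} inputs).
#' @param seed integer seed for weight initialization.
#' @param decay weight-decay regularization (default 0.01).
#' @param segment_iters,max_segments,patience early-stopping schedule:
#'   optimizer iterations per segment, maximum number of segments, and the
#'   number of non-improving segments tolerated before stopping.
#' @return an object of class \code{ql_network} with the fitted weights,
#'   scaling parameters, architecture, seed and the correlation coefficients
#'   \code{r_train}, \code{r_test}, \code{r_valid}, \code{r_combined}.
#' @export
train_network <- function(matrix, split, m = 2L, seed = 1L, decay = 0.01,
                          segment_iters = 100L, max_segments = 6L,
                          patience = 2L) {
  x <- matrix$x; y <- matrix$y
  keep <- !is.na(y)
  if (!all(keep)) { x <- x[keep, , drop = FALSE]; y <- y[keep]; split <- split[keep] }
  k <- ncol(x)
  if (m >= max(2L, k + 1L)) stop("hidden layer must be narrower than the input layer")
  tr <- split == "train"
  mu <- colMeans(x[tr, , drop = FALSE])
  sdev <- apply(x[tr, , drop = FALSE], 2, stats::sd)
  sdev[sdev == 0] <- 1
  xs <- scale(x, center = mu, scale = sdev)
  ymu <- mean(y[tr]); ysd <- stats::sd(y[tr])
  degenerate_y <- is.na(ysd) || ysd == 0
  if (degenerate_y) ysd <- 1
  ys <- (y - ymu) / ysd

  set.seed(seed)
  nw <- (k + 1L) * m + (m + 1L)
  wts <- stats::runif(nw, -0.5, 0.5)
  best_wts <- wts; best_err <- Inf; bad <- 0L
  fit <- NULL
  for (seg in seq_len(max_segments)) {
    fit <- nnet::nnet(x = xs[tr, , drop = FALSE], y = ys[tr], size = m,
                      linout = TRUE, decay = decay, maxit = segment_iters,
                      Wts = wts, trace = FALSE)
    if (!all(is.finite(fit$wts)))
      stop("non-finite weights during training (m=", m, ", seed=", seed, ")")
    wts <- fit$wts
    pred_test <- as.numeric(stats::predict(fit, xs[split == "test", , drop = FALSE]))
    err <- mean((pred_test - ys[split == "test"])^2)
    if (!is.finite(err))
      stop("non-finite test loss during training (m=", m, ", seed=", seed, ")")
    if (err < best_err - 1e-10) { best_err <- err; best_wts <- wts; bad <- 0L }
    else { bad <- bad + 1L; if (bad >= patience) break }
  }
  fit$wts <- best_wts

  net <- structure(list(
    fit = fit, m = m, k = k, seed = seed, decay = decay,
    labels = colnames(x), x_center = mu, x_scale = sdev,
    y_center = ymu, y_scale = ysd, degenerate = degenerate_y),
    class = "ql_network")
  pred <- predict_network(net, x)
  net$r_train <- safe_cor(pred[tr], y[tr])
  net$r_test <- safe_cor(pred[split == "test"], y[split == "test"])
  net$r_valid <- safe_cor(pred[split == "validation"], y[split == "validation"])
  net$r_combined <- safe_cor(pred, y)
  net
}

# forward pass on raw (unscaled) inputs
predict_network <- function(net, x) {
  if (is.null(dim(x))) x <- rbind(x)
  xs <- scale(x[, net$labels, drop = FALSE],
              center = net$x_center, scale = net$x_scale)
  as.numeric(stats::predict(net$fit, xs)) * net$y_scale + net$y_center
}

#' @export
print.ql_network <- function(x, ...) {
  cat(sprintf("<ql_network %d-%d-1  r_train=%.3f r_test=%.3f r_valid=%.3f r_combined=%.3f>\n",
              x$k, x$m, x$r_train, x$r_test, x$r_valid, x$r_combined))
  invisible(x)
}

#' @export
predict.ql_network <- function(object, newdata, ...) {
  if (inherits(newdata, "ql_matrix")) newdata <- newdata$x
  predict_network(object, newdata)
}
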