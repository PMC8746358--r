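#' Train a population of networks and keep the best performers
#'
#' Trains \code{n_total} narrow-throat networks with per-network derived
#' seeds, scanning the hidden-layer width over \code{m_range} (restricted to
#' \code{m < k/3} where possible so the throat stays narrow), and retains the
#' \code{n_keep} networks with the highest selection score
#' \code{min(r_train, r_test, r_valid)}.
#'
#' @param matrix a \code{ql_matrix}.
#' @param split partition factor from [split_dataset()].
#' @param n_total,n_keep population size and number retained.
#' @param m_range candidate hidden-layer widths.
#' @param seed master seed; per-network seeds are derived by counter.
#' @param ... passed to [train_network()].
#' @return list of \code{ql_network}, ordered by decreasing selection score
#'   (ties by training order).
#' @export
train_population <- function(matrix, split, n_total = 100L, n_keep = 25L,
                             m_range = 2:5, seed = 1L, ...) {
  if (n_keep > n_total) stop("n_keep must not exceed n_total")
  k <- ncol(matrix$x)
  allowed <- m_range[m_range < k / 3]
  if (length(allowed) == 0L)
    allowed <- max(1L, min(min(m_range), floor(k / 2)))
  nets <- vector("list", n_total)
  failures <- 0L
  for (b in seq_len(n_total)) {
    sb <- derive_seed(seed, b)
    set.seed(sb)
    m <- if (length(allowed) == 1L) allowed else sample(allowed, 1L)
    nets[[b]] <- tryCatch(
      train_network(matrix, split, m = m, seed = sb, ...),
      error = function(e) { failures <<- failures + 1L; NULL })
  }
  if (failures > n_total / 2)
    stop(sprintf("%d of %d network trainings failed", failures, n_total))
  nets <- Filter(Negate(is.null), nets)
  score <- vapply(nets, selection_score, 0)
  keep <- order(-score)[seq_len(min(n_keep, length(nets)))]  # stable ties
  out <- nets[keep]
  # structured training log: one record per trained network
  attr(out, "log") <- data.frame(
    seed = vapply(nets, function(n) as.integer(n$seed), 0L),
    m = vapply(nets, function(n) as.integer(n$m), 0L),
    r_train = vapply(nets, function(n) n$r_train, 0),
    r_test = vapply(nets, function(n) n$r_test, 0),
    r_valid = vapply(nets, function(n) n$r_valid, 0),
    kept = seq_along(nets) %in% keep)
  out
}

selection_score <- function(net) {
  r3 <- c(net$r_train, net$r_test, net$r_valid)
  if (any(is.na(r3))) return(-Inf)
  min(r3)
}

#' Select the best network of a population
#'
#' The pick is the network maximizing the minimum of the three partition
#' correlations; ties are broken by the mean of the three, then by training
#' order (deterministic).
#'
#' @param networks non-empty list of \code{ql_network}.
#' @return a single \code{ql_network}.
#' @export
select_best <- function(networks) {
  if (length(networks) == 0L) stop("empty network list")
  score <- vapply(networks, selection_score, 0)
  mean3 <- vapply(networks, function(n) {
    r3 <- c(n$r_train, n$r_test, n$r_valid)
    if (any(is.na(r3))) -Inf else mean(r3)
  }, 0)
  networks[[order(-score, -mean3)[1]]]
}

#' Per-input sensitivity of a trained network
#'
#' For each input descriptor, the dimensionless sensitivity index is the
#' ratio \code{Sens_i = E_i / E_0}, where \code{E_0} is the sum-of-squares
#' prediction error on the chosen partition and \code{E_i} is the same error
#' after replacing column i by its training-partition mean.  An input the
#' network ignores has \code{Sens = 1} exactly; informative inputs have
#' \code{Sens > 1}; inputs whose removal *reduces* the error score below 1
#' and are candidates for pruning.
#'
#' @param network a \code{ql_network}.
#' @param matrix the \code{ql_matrix} the network was trained on.
#' @param split the partition factor used in training.
#' @param partition rows the errors are computed on: \code{"holdout"}
#'   (test + validation, the default), \code{"combined"} (all rows) or
#'   \code{"train"}.  On the training rows of a flexible network the
#'   mean-replacement error almost always increases, so \code{"train"}
#'   (and, diluted, \code{"combined"}) overstates the relevance of inputs
#'   the network merely overfits; the held-out rows measure whether an
#'   input carries transferable signal.
#' @return a data frame of class \code{sens_report} with columns
#'   \code{label} and \code{sens}, sorted by decreasing sensitivity; the
#'   reference error is attached as attribute \code{e0}.
#' @export
sensitivity <- function(network, matrix, split,
                        partition = c("holdout", "combined", "train")) {
  partition <- match.arg(partition)
  x <- matrix$x; y <- matrix$y
  keep <- !is.na(y)
  x <- x[keep, , drop = FALSE]; y <- y[keep]; split <- split[keep]
  if (!identical(colnames(x), network$labels))
    stop("matrix columns do not match the network inputs")
  rows <- switch(partition,
                 train = split == "train",
                 holdout = split != "train",
                 combined = rep(TRUE, length(y)))
  xr <- x[rows, , drop = FALSE]; yr <- y[rows]
  e0 <- sum((predict_network(network, xr) - yr)^2)
  flagged <- e0 <= 0
  e0r <- max(e0, .Machine$double.eps)
  sens <- vapply(seq_len(ncol(xr)), function(i) {
    xi <- xr
    xi[, i] <- network$x_center[[i]]   # training-partition mean
    ei <- sum((predict_network(network, xi) - yr)^2)
    ei / e0r
  }, 0)
  out <- data.frame(label = colnames(xr), sens = sens,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$sens), ]
  rownames(out) <- NULL
  class(out) <- c("sens_report", "data.frame")
  attr(out, "e0") <- e0
  attr(out, "partition") <- partition
  attr(out, "degenerate") <- flagged
  out
}
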