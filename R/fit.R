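#' Control parameters for the iterative pruning fit
#'
#' @param ratios train/test/validation fractions (default 70/15/15).
#' @param n_total,n_keep networks trained and retained per iteration.
#' @param m_range candidate hidden-layer widths (scanned subject to
#'   \code{m < k/3}).
#' @param prune_threshold inputs with \code{Sens <} this value are removed
#'   each iteration (strict inequality; default 1.0).
#' @param sens_threshold significance threshold for pharmacophore membership
#'   (default 1.1; must be \code{>= prune_threshold}).
#' @param max_iter hard cap on iterations (default 50; the loop also stops
#'   as soon as no input is pruned).
#' @param freeze_split if \code{TRUE} the same split is reused across
#'   iterations; by default each iteration re-splits with a fresh derived
#'   seed, re-entering the procedure from its first step.
#' @param sens_partition rows the sensitivity errors are computed on:
#'   \code{"auto"} (default) uses the held-out test+validation rows whenever
#'   at least 20 are available -- enough for a stable error ratio -- and
#'   falls back to the pooled set on smaller samples; \code{"holdout"},
#'   \code{"combined"} and \code{"train"} force a choice.
#' @param decay,segment_iters,max_segments,patience per-network training
#'   schedule, passed to [train_network()].
#' @return a list of class \code{qlnet_control}.
#' @export
qlnet_control <- function(ratios = c(0.70, 0.15, 0.15),
                          n_total = 100L, n_keep = 25L, m_range = 2:5,
                          prune_threshold = 1.0, sens_threshold = 1.1,
                          max_iter = 50L, freeze_split = FALSE,
                          sens_partition = "auto",
                          decay = 0.01, segment_iters = 100L,
                          max_segments = 6L, patience = 2L) {
  if (sens_threshold < prune_threshold)
    stop("sens_threshold must be >= prune_threshold")
  if (max_iter < 1L) stop("max_iter must be >= 1")
  structure(as.list(environment()), class = "qlnet_control")
}

#' Fit a QL-descriptor network with iterative sensitivity pruning
#'
#' The core estimator: starting from a compounds-by-descriptors count matrix
#' and an activity vector, each iteration (i) splits the data 70/15/15,
#' (ii) trains a population of narrow-throat k-m-1 perceptrons and keeps the
#' best quarter, (iii) picks the single best network by the minimum of its
#' three partition correlations, (iv) computes per-input sensitivities and
#' removes every descriptor with \code{Sens <} the pruning threshold.  The
#' loop ends when no descriptor is removed (or at \code{max_iter}); the
#' surviving descriptors with \code{Sens >=} the significance threshold form
#' the pharmacophore.
#'
#' @param x a \code{ql_matrix} from [build_descriptor_matrix()], or a plain
#'   numeric matrix of descriptor counts (with column names).
#' @param y activity vector (ignored when \code{x} is a \code{ql_matrix}
#'   that already carries one).
#' @param control a [qlnet_control()] list.
#' @param seed master seed; every stochastic stage derives its seed from it,
#'   so a rerun with the same inputs is bit-identical.
#' @return an object of class \code{qlnet} with components
#'   \code{iterations} (one row per iteration: descriptor count, the three
#'   correlations and the combined-set correlation of the best network,
#'   number pruned), \code{network} (final best \code{ql_network}),
#'   \code{sens} (final sensitivity report), \code{pharmacophore},
#'   \code{matrix} (final pruned \code{ql_matrix}), \code{pruned}
#'   (per-iteration pruned labels with their Sens values).
#' @examples
#' \donttest{
#' syn <- generate_matrix(synthetic_spec(n_compounds = 60, n_descriptors = 10,
#'                                       planted = 1:2, seed = 7))
#' fit <- qlnet(syn$matrix, control = qlnet_control(n_total = 10, n_keep = 3),
#'              seed = 7)
#' print(fit)
#' }
#' @export
qlnet <- function(x, y = NULL, control = qlnet_control(), seed = 1L) {
  mat <- if (inherits(x, "ql_matrix")) x
         else structure(list(x = as.matrix(x), y = y, dropped = character(0)),
                        class = "ql_matrix")
  if (!is.null(y) && inherits(x, "ql_matrix")) mat$y <- y
  if (is.null(mat$y) || all(is.na(mat$y))) stop("no activity values supplied")
  if (is.null(colnames(mat$x))) stop("descriptor matrix must have column names")
  keep_rows <- !is.na(mat$y)
  mat$x <- mat$x[keep_rows, , drop = FALSE]
  mat$y <- mat$y[keep_rows]
  if (ncol(mat$x) < 2L) stop("need at least 2 descriptor columns")

  ctrl <- control
  if (ctrl$sens_partition == "auto") {
    n_holdout <- nrow(mat$x) - floor(nrow(mat$x) * ctrl$ratios[1])
    ctrl$sens_partition <- if (n_holdout >= 20L) "holdout" else "combined"
  }
  cur <- mat
  iterations <- list(); pruned_log <- list()
  best <- NULL; sens_rep <- NULL; split <- NULL
  for (it in seq_len(ctrl$max_iter)) {
    split_seed <- if (ctrl$freeze_split) derive_seed(seed, 0L)
                  else derive_seed(seed, 100000L + it)
    split <- split_dataset(nrow(cur$x), ctrl$ratios, seed = split_seed)
    pop <- train_population(cur, split, n_total = ctrl$n_total,
                            n_keep = ctrl$n_keep, m_range = ctrl$m_range,
                            seed = derive_seed(seed, it),
                            decay = ctrl$decay,
                            segment_iters = ctrl$segment_iters,
                            max_segments = ctrl$max_segments,
                            patience = ctrl$patience)
    best <- select_best(pop)
    sens_rep <- sensitivity(best, cur, split, partition = ctrl$sens_partition)
    drop <- sens_rep$label[sens_rep$sens < ctrl$prune_threshold]
    iterations[[it]] <- data.frame(
      iteration = it, k = ncol(cur$x), m = best$m,
      r_train = best$r_train, r_test = best$r_test, r_valid = best$r_valid,
      r_combined = best$r_combined, n_pruned = length(drop))
    pruned_log[[it]] <- sens_rep[sens_rep$label %in% drop,
                                 c("label", "sens"), drop = FALSE]
    if (length(drop) == 0L) break
    if (length(drop) == ncol(cur$x)) {
      err <- simpleError("all descriptor columns pruned")
      err$sens_report <- sens_rep
      stop(err)
    }
    cur$x <- cur$x[, setdiff(colnames(cur$x), drop), drop = FALSE]
  }
  ph <- extract_pharmacophore(sens_rep, best, threshold = ctrl$sens_threshold)
  structure(list(
    iterations = do.call(rbind, iterations),
    pruned = pruned_log,
    network = best, sens = sens_rep, split = split,
    pharmacophore = ph, matrix = cur,
    seed = seed, control = ctrl, call = match.call()),
    class = "qlnet")
}

#' Extract the pharmacophore from a terminal sensitivity report
#'
#' Descriptors whose sensitivity meets the significance threshold, sorted by
#' decreasing Sens.  An empty result is valid and carries a warning.
#'
#' @param report a \code{sens_report} from the terminal iteration.
#' @param network the network the report was computed from (stored as
#'   provenance).
#' @param threshold significance threshold (default 1.1).
#' @return an object of class \code{pharmacophore}: \code{descriptors}
#'   (data frame \code{label}, \code{sens}), \code{threshold},
#'   \code{network}.
#' @export
extract_pharmacophore <- function(report, network = NULL, threshold = 1.1) {
  d <- report[report$sens >= threshold, c("label", "sens"), drop = FALSE]
  d <- d[order(-d$sens), , drop = FALSE]
  rownames(d) <- NULL
  if (nrow(d) == 0L) warning("no descriptor reaches the significance threshold")
  structure(list(descriptors = as.data.frame(d), threshold = threshold,
                 network = network, source = "fitted"),
            class = "pharmacophore")
}

#' @export
print.pharmacophore <- function(x, ...) {
  cat(sprintf("Pharmacophore (%d descriptors, Sens >= %.2f)\n",
              nrow(x$descriptors), x$threshold))
  for (i in seq_len(nrow(x$descriptors)))
    cat(sprintf("  %-26s Sens = %.2f\n",
                x$descriptors$label[i], x$descriptors$sens[i]))
  invisible(x)
}

# ---- qlnet methods ---------------------------------------------------------

#' @export
print.qlnet <- function(x, ...) {
  ni <- nrow(x$iterations)
  cat(sprintf("qlnet: %d iteration(s), %d -> %d descriptors\n",
              ni, x$iterations$k[1], ncol(x$matrix$x)))
  cat(sprintf("final network %d-%d-1: R(train/test/valid) = %.3f/%.3f/%.3f, combined R = %.3f\n",
              x$network$k, x$network$m, x$network$r_train,
              x$network$r_test, x$network$r_valid, x$network$r_combined))
  cat(sprintf("pharmacophore: %d descriptor(s) with Sens >= %.2f\n",
              nrow(x$pharmacophore$descriptors), x$pharmacophore$threshold))
  invisible(x)
}

#' @export
summary.qlnet <- function(object, ...) {
  structure(list(iterations = object$iterations,
                 sens = object$sens,
                 pharmacophore = object$pharmacophore,
                 network = object$network), class = "summary.qlnet")
}

#' @export
print.summary.qlnet <- function(x, ...) {
  cat("Iteration trace:\n")
  print(x$iterations, row.names = FALSE, digits = 3)
  cat("\nTerminal sensitivities:\n")
  print(as.data.frame(x$sens), row.names = FALSE, digits = 3)
  cat("\n")
  print(x$pharmacophore)
  invisible(x)
}

#' @export
coef.qlnet <- function(object, ...) {
  stats::setNames(object$sens$sens, object$sens$label)
}

#' @export
predict.qlnet <- function(object, newdata, ...) {
  if (inherits(newdata, "ql_matrix")) newdata <- newdata$x
  newdata <- as.matrix(newdata)
  missing <- setdiff(object$network$labels, colnames(newdata))
  if (length(missing)) {
    # descriptors absent from new compounds enter as zero counts
    pad <- matrix(0, nrow(newdata), length(missing),
                  dimnames = list(rownames(newdata), missing))
    newdata <- cbind(newdata, pad)
  }
  predict_network(object$network, newdata)
}

#' @export
fitted.qlnet <- function(object, ...) {
  stats::setNames(predict_network(object$network, object$matrix$x),
                  rownames(object$matrix$x))
}

#' @export
residuals.qlnet <- function(object, ...) {
  object$matrix$y - fitted(object)
}

#' @export
plot.qlnet <- function(x, which = c("trace", "sens"), ...) {
  which <- match.arg(which)
  if (which == "trace") {
    it <- x$iterations
    graphics::plot(it$iteration, it$r_combined, type = "b", pch = 19,
                   xlab = "iteration", ylab = "combined-set R",
                   ylim = range(c(it$r_combined, it$r_valid), na.rm = TRUE), ...)
    graphics::lines(it$iteration, it$r_valid, type = "b", lty = 2, pch = 1)
    graphics::legend("bottomright", legend = c("combined", "validation"),
                     lty = c(1, 2), pch = c(19, 1), bty = "n")
  } else {
    s <- x$sens
    graphics::barplot(rev(s$sens), names.arg = rev(s$label), horiz = TRUE,
                      las = 1, xlab = "Sens", ...)
    graphics::abline(v = x$pharmacophore$threshold, lty = 2)
  }
  invisible(x)
}

#' Serialize a fitted network to JSON
#'
#' Architecture, scaling, weights, correlations and seed: everything needed
#' to reproduce predictions exactly.
#'
#' @param network a \code{ql_network}.
#' @param path output file.
#' @export
write_network_json <- function(network, path) {
  obj <- list(k = network$k, m = network$m, seed = network$seed,
              decay = network$decay, labels = network$labels,
              x_center = as.numeric(network$x_center),
              x_scale = as.numeric(network$x_scale),
              y_center = network$y_center, y_scale = network$y_scale,
              wts = network$fit$wts,
              r = c(train = network$r_train, test = network$r_test,
                    valid = network$r_valid, combined = network$r_combined))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
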