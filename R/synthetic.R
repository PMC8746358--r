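#' Specification for a synthetic descriptor matrix
#'
#' Describes a planted-signal benchmark: a compounds-by-descriptors count
#' matrix with independent binomial counts per column, and an activity that
#' depends linearly on a small planted subset of columns plus Gaussian noise.
#' The default activity scale emulates thrombin-time-like values: a baseline
#' of 25 seconds plus the planted signal.
#'
#' @param n_compounds,n_descriptors matrix dimensions (defaults 100 x 40,
#'   the regime at which recovery statistics are meaningful; use 23 to mimic
#'   the experimental sample size).
#' @param planted indices (or count) of informative descriptors; default 5.
#' @param beta effect sizes per planted descriptor, recycled (default 8:
#'   seconds of thrombin-time shift per descriptor occurrence).
#' @param occ_prob per-column occurrence probability (default 0.4).
#' @param max_mult maximum per-compound multiplicity of a descriptor
#'   (default 3; counts are Binomial(max_mult, occ_prob)).
#' @param noise_sd_frac noise standard deviation as a fraction of the
#'   noise-free signal's standard deviation (default 0.1).
#' @param baseline activity baseline (default 25, seconds).
#' @param seed integer seed.
#' @return a list of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_compounds = 100L, n_descriptors = 40L,
                           planted = 5L, beta = 8, occ_prob = 0.4,
                           max_mult = 3L, noise_sd_frac = 0.1,
                           baseline = 25, seed = 1L) {
  if (length(planted) == 1L) planted <- seq_len(planted)  # a count
  planted <- as.integer(planted)
  if (any(planted < 1L | planted > n_descriptors))
    stop("planted indices out of range")
  if (n_compounds < 7L) stop("need at least 7 compounds")
  if (noise_sd_frac < 0) stop("noise sd must be >= 0")
  beta <- rep_len(beta, length(planted))
  if (all(beta == 0) && noise_sd_frac == 0)
    stop("degenerate spec: zero effects and zero noise")
  structure(list(n_compounds = as.integer(n_compounds),
                 n_descriptors = as.integer(n_descriptors),
                 planted = planted, beta = beta, occ_prob = occ_prob,
                 max_mult = as.integer(max_mult),
                 noise_sd_frac = noise_sd_frac, baseline = baseline,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic descriptor matrix with planted effects
#'
#' @param spec a [synthetic_spec()].
#' @return a list of class \code{synthetic_dataset}: \code{matrix} (a
#'   \code{ql_matrix} with descriptor columns \code{D01..}), \code{planted}
#'   (planted column labels), \code{spec}.
#' @examples
#' d <- generate_matrix(synthetic_spec(n_compounds = 20, seed = 3))
#' dim(d$matrix$x)
#' @export
generate_matrix <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_compounds; k <- spec$n_descriptors
  x <- matrix(stats::rbinom(n * k, spec$max_mult, spec$occ_prob), n, k)
  labels <- sprintf("D%02d", seq_len(k))
  dimnames(x) <- list(sprintf("S%03d", seq_len(n)), labels)
  signal <- as.numeric(x[, spec$planted, drop = FALSE] %*% spec$beta)
  ssd <- stats::sd(signal)
  if (is.na(ssd) || ssd == 0) ssd <- 1
  noise <- stats::rnorm(n, 0, spec$noise_sd_frac * ssd)
  y <- spec$baseline + signal + noise
  mat <- structure(list(x = x, y = y, dropped = character(0)),
                   class = "ql_matrix")
  structure(list(matrix = mat, planted = labels[spec$planted], spec = spec),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset: %d x %d, %d planted columns, noise %.2f sd(signal)>\n",
              nrow(x$matrix$x), ncol(x$matrix$x), length(x$planted),
              x$spec$noise_sd_frac))
  invisible(x)
}

#' Generate random azole-like test molecules
#'
#' Draws small N-heterocyclic structures from a fixed grammar (azole /
#' pyrimidinone / benzene scaffolds with nitro, ester, methyl, hydroxyl,
#' amine or aryl decorations), parses each and returns them as compound
#' records.  Used to exercise the descriptor pipeline on varied but valid
#' chemistry without external structure files.
#'
#' @param n number of molecules.
#' @param seed integer seed.
#' @return a \code{compound_set} list of length \code{n}.
#' @export
generate_molecule_set <- function(n, seed = 1L) {
  n <- as.integer(n)
  if (n == 0L) {
    out <- list(); class(out) <- c("compound_set", "list"); return(out)
  }
  set.seed(seed)
  scaffolds <- c("c1cc(%s)co1", "c1cc(%s)cs1", "c1ccc(%s)cn1",
                 "c1ccc(%s)cc1%s", "Cc1nc(%s)c(%s)o1",
                 "O=c1cc(%s)[nH]c(%s)n1")
  subs <- c("[N+](=O)[O-]", "C(=O)OCC", "C", "O", "N", "C#N", "OC",
            "CC(C)C", "-c2ccco2", "-c2ccccc2")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sc <- sample(scaffolds, 1L)
    nslot <- lengths(regmatches(sc, gregexpr("%s", sc, fixed = TRUE)))
    smi <- do.call(sprintf, c(list(sc), as.list(sample(subs, nslot, replace = TRUE))))
    g <- tryCatch(parse_smiles(smi, name = sprintf("synth%03d", i)),
                  error = function(e)
                    stop("molecule grammar produced unparseable output: ", smi))
    out[[i]] <- list(id = sprintf("synth%03d", i), structure = g,
                     structure_full = g, tt = NA_real_)
  }
  class(out) <- c("compound_set", "list")
  out
}

#' Recovery metrics against a planted descriptor set
#'
#' Precision and recall of (a) the descriptors retained at termination and
#' (b) the significant (\code{Sens >=} threshold) set, against the planted
#' ground truth of a synthetic dataset.
#'
#' @param fit a \code{qlnet} fit run on a synthetic dataset.
#' @param truth character vector of planted column labels.
#' @return a data frame with rows \code{retained} and \code{significant}
#'   and columns \code{n}, \code{precision}, \code{recall}.
#' @export
recovery_metrics <- function(fit, truth) {
  sets <- list(retained = colnames(fit$matrix$x),
               significant = fit$pharmacophore$descriptors$label)
  rows <- lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    tp <- length(intersect(s, truth))
    data.frame(set = nm, n = length(s),
               precision = if (length(s)) tp / length(s) else 0,
               recall = if (length(truth)) tp / length(truth) else 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$set
  out
}
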