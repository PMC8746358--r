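#' Build a compounds-by-descriptors matrix
#'
#' Enumerates QL descriptors for every compound and assembles the occurrence
#' count matrix used as neural-network input.  Columns are the union of
#' descriptors observed in any compound, sorted lexicographically; constant
#' columns (identical value in every compound, including all-zero) carry no
#' information for regression and are removed with a message.
#'
#' @param compounds a list of compound records as returned by
#'   [load_compound_set()]: each element has \code{id}, \code{structure}
#'   (a [molgraph]) and optionally \code{tt} (activity).
#' @param catalog a [fragment_catalog].
#' @param rules a [ql_rules] object.
#' @param binarize logical; if \code{TRUE} counts are reduced to 0/1 presence
#'   flags (default \code{FALSE}: multiplicities are kept).
#' @param drop_constant remove constant columns (default \code{TRUE}).
#' @return a list of class \code{ql_matrix}: \code{x} (integer matrix,
#'   rownames = compound ids), \code{y} (activity vector, \code{NA} where
#'   absent), \code{dropped} (labels of removed constant columns).
#' @export
build_descriptor_matrix <- function(compounds, catalog = fragment_catalog(),
                                    rules = ql_rules(), binarize = FALSE,
                                    drop_constant = TRUE) {
  if (length(compounds) < 2L) stop("need at least 2 compounds")
  ids <- vapply(compounds, function(cp) cp$id, "")
  if (anyDuplicated(ids)) stop("duplicate compound ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  counts <- lapply(compounds, function(cp)
    enumerate_ql_descriptors(cp$structure, catalog, rules))
  labels <- sort(unique(unlist(lapply(counts, names))))
  if (length(labels) == 0L) stop("no QL descriptor observed in any compound")
  x <- matrix(0L, nrow = length(compounds), ncol = length(labels),
              dimnames = list(ids, labels))
  for (i in seq_along(counts)) {
    ci <- counts[[i]]
    if (length(ci)) x[i, names(ci)] <- as.integer(ci)
  }
  if (binarize) x <- (x > 0L) * 1L
  dropped <- character(0)
  if (drop_constant) {
    const <- apply(x, 2, function(col) length(unique(col)) == 1L)
    dropped <- colnames(x)[const]
    if (length(dropped))
      message(sprintf("dropping %d constant descriptor column(s)", length(dropped)))
    x <- x[, !const, drop = FALSE]
    if (ncol(x) == 0L) stop("all descriptor columns are constant")
  }
  y <- vapply(compounds, function(cp)
    if (is.null(cp$tt) || is.na(cp$tt)) NA_real_ else as.numeric(cp$tt), 0)
  structure(list(x = x, y = y, dropped = dropped,
                 catalog = catalog, rules = rules),
            class = "ql_matrix")
}

#' @export
print.ql_matrix <- function(x, ...) {
  cat(sprintf("<ql_matrix: %d compounds x %d descriptors, %d with activity>\n",
              nrow(x$x), ncol(x$x), sum(!is.na(x$y))))
  invisible(x)
}

#' Count pharmacophore entries in one structure
#'
#' Restricts QL descriptor enumeration to a set of pharmacophore descriptors
#' and reports, per descriptor, how many entries (occurrence pairs) the
#' structure contains.
#'
#' @param mol a normalized [molgraph].
#' @param pharmacophore character vector of QL descriptor labels
#'   (as rendered by [ql_label()]), or a \code{pharmacophore} object.
#' @param catalog,rules matching configuration (must be the configuration the
#'   pharmacophore was derived with).
#' @return a list of class \code{pharm_match}: \code{id}, \code{counts}
#'   (named integer vector over the pharmacophore descriptors),
#'   \code{entries} (total) and \code{types} (number of descriptors present).
#' @export
count_pharmacophore_entries <- function(mol, pharmacophore,
                                        catalog = fragment_catalog(),
                                        rules = ql_rules()) {
  labels <- pharmacophore_labels(pharmacophore)
  if (length(labels) == 0L) stop("empty pharmacophore")
  all_counts <- enumerate_ql_descriptors(mol, catalog, rules)
  counts <- structure(integer(length(labels)), names = labels)
  hit <- intersect(names(all_counts), labels)
  counts[hit] <- as.integer(all_counts[hit])
  structure(list(id = mol$name, counts = counts,
                 entries = sum(counts), types = sum(counts > 0L)),
            class = "pharm_match")
}

#' @export
print.pharm_match <- function(x, ...) {
  cat(sprintf("%s: %d entries of %d types\n",
              if (nzchar(x$id)) x$id else "<structure>", x$entries, x$types))
  for (lab in names(x$counts))
    if (x$counts[[lab]] > 0) cat(sprintf("  %-24s %d\n", lab, x$counts[[lab]]))
  invisible(x)
}

pharmacophore_labels <- function(p) {
  if (inherits(p, "pharmacophore")) p$descriptors$label else as.character(p)
}

#' Pharmacophore coverage table
#'
#' Applies [count_pharmacophore_entries()] to a list of compounds and returns
#' the entry/type counts as a data frame (one row per compound, one column
#' per pharmacophore descriptor plus totals).
#'
#' @param compounds list of compound records.
#' @param pharmacophore descriptor labels or a \code{pharmacophore} object.
#' @param catalog,rules matching configuration.
#' @return a data frame with columns \code{id}, one per descriptor,
#'   \code{entries}, \code{types}.
#' @export
pharmacophore_coverage_table <- function(compounds, pharmacophore,
                                         catalog = fragment_catalog(),
                                         rules = ql_rules()) {
  labels <- pharmacophore_labels(pharmacophore)
  if (length(labels) == 0L) stop("empty pharmacophore")
  rows <- lapply(compounds, function(cp) {
    m <- count_pharmacophore_entries(cp$structure, labels, catalog, rules)
    c(list(id = cp$id), as.list(m$counts),
      list(entries = m$entries, types = m$types))
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
  if (is.null(df)) df <- data.frame(id = character(0))
  rownames(df) <- NULL
  df
}
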