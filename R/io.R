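#' Write a descriptor matrix as CSV with a JSON sidecar
#'
#' The CSV holds compounds as rows (first column \code{id}, then one integer
#' column per descriptor, then \code{tt} when activity is present).  The
#' sidecar (\code{<path>.json}) records the matching configuration: catalog
#' labels and patterns, a content hash of the catalog, the pairing rules and
#' the dropped constant columns, so a matrix file is self-describing.
#'
#' @param mat a \code{ql_matrix}.
#' @param path CSV output path.
#' @return \code{path}, invisibly.
#' @export
write_descriptor_matrix <- function(mat, path) {
  df <- data.frame(id = rownames(mat$x), mat$x, check.names = FALSE)
  if (!all(is.na(mat$y))) df$tt <- mat$y
  utils::write.csv(df, path, row.names = FALSE)
  catalog <- mat$catalog
  sidecar <- list(
    descriptors = colnames(mat$x),
    dropped_constant = mat$dropped,
    rules = if (!is.null(mat$rules)) unclass(mat$rules),
    catalog = if (!is.null(catalog))
      list(labels = catalog$label, patterns = catalog$pattern,
           hash = catalog_hash(catalog)))
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

# order-stable content hash of a catalog (no external digest dependency:
# a small rolling polynomial over the label/pattern text)
catalog_hash <- function(catalog) {
  txt <- paste(catalog$label, catalog$pattern, collapse = ";", sep = "=")
  h <- 0
  for (code in utf8ToInt(txt)) h <- (h * 31 + code) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write the full output bundle of a fitted pipeline
#'
#' Emits, under \code{dir}: \code{iterations.csv} (the per-iteration trace),
#' \code{pharmacophore.json} (significant descriptors with Sens values and
#' threshold), \code{best_network.json} (weights and scaling, see
#' [write_network_json()]), and, when a compound set is supplied,
#' \code{coverage.csv} (pharmacophore entry counts per compound).
#'
#' @param fit a \code{qlnet} object.
#' @param dir output directory (created if needed).
#' @param compounds optional compound list for the coverage table.
#' @param catalog,rules matching configuration for the coverage table.
#' @return \code{dir}, invisibly.
#' @export
write_qlnet_outputs <- function(fit, dir, compounds = NULL,
                                catalog = fragment_catalog(),
                                rules = ql_rules()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(fit$iterations, file.path(dir, "iterations.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(threshold = fit$pharmacophore$threshold,
         descriptors = fit$pharmacophore$descriptors,
         seed = fit$seed),
    file.path(dir, "pharmacophore.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  write_network_json(fit$network, file.path(dir, "best_network.json"))
  if (!is.null(compounds) && nrow(fit$pharmacophore$descriptors) > 0) {
    tab <- pharmacophore_coverage_table(compounds, fit$pharmacophore,
                                        catalog, rules)
    utils::write.csv(tab, file.path(dir, "coverage.csv"), row.names = FALSE)
  }
  invisible(dir)
}
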