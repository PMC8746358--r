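#' Load a compound set from a table or SDF file
#'
#' Reads a CSV/TSV table (columns \code{id}, \code{smiles}, optional
#' \code{tt}) or an SDF V2000 file into a list of compound records.  Each
#' record holds \code{id}, \code{structure} (a salt-stripped, normalized
#' [molgraph]), \code{structure_full} (before salt stripping), and \code{tt}
#' (activity in seconds, \code{NA} when absent).  Row order is preserved.
#'
#' @param path file path; format decided by extension (\code{.sdf} vs
#'   delimited text) unless \code{format} is given.
#' @param format \code{"auto"}, \code{"table"} or \code{"sdf"}.
#' @param strip_salts reduce each structure to its parent component
#'   (default \code{TRUE}).
#' @param neutralize re-protonate the stripped parent ion to the neutral
#'   form (default \code{TRUE}); see [neutralize_parent()].
#' @return list of compound records (class \code{compound_set}).
#' @export
load_compound_set <- function(path, format = c("auto", "table", "sdf"),
                              strip_salts = TRUE, neutralize = TRUE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.sdf$", path, ignore.case = TRUE)) "sdf" else "table"
  recs <- if (format == "sdf") read_sdf_records(path) else read_table_records(path)
  ids <- vapply(recs, function(r) r$id, "")
  if (anyDuplicated(ids))
    stop("duplicate compound ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    g <- tryCatch(recs[[i]]$graph, error = function(e) e)
    if (inherits(g, "error") || is.null(g))
      stop(sprintf("row %d (id '%s'): unparsable structure", i, recs[[i]]$id))
    parent <- if (strip_salts) strip_counterions(g) else g
    if (neutralize) parent <- neutralize_parent(parent)
    out[[i]] <- list(id = recs[[i]]$id, structure = parent,
                     structure_full = g, tt = recs[[i]]$tt)
  }
  class(out) <- c("compound_set", "list")
  out
}

read_table_records <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "\"")
  if (nrow(df) == 0L) return(list())
  names(df) <- tolower(names(df))
  if (!all(c("id", "smiles") %in% names(df)))
    stop("compound table must have 'id' and 'smiles' columns")
  lapply(seq_len(nrow(df)), function(i) {
    g <- tryCatch(parse_smiles(df$smiles[i], name = df$id[i]),
                  error = function(e)
                    stop(sprintf("row %d (id '%s'): %s", i, df$id[i],
                                 conditionMessage(e)), call. = FALSE))
    list(id = as.character(df$id[i]), graph = g,
         tt = if ("tt" %in% names(df)) suppressWarnings(as.numeric(df$tt[i]))
              else NA_real_)
  })
}

# minimal SDF V2000 reader: counts line, atom block (element), bond block,
# M  CHG lines, optional <tt> data field
read_sdf_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (i + 3L > length(lines)) break
    name <- trimws(lines[i])
    counts <- lines[i + 3L]
    na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
    nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
    if (is.na(na) || is.na(nb)) stop(sprintf("bad SDF counts line at line %d", i + 3L))
    el <- character(na); chg <- integer(na)
    for (k in seq_len(na))
      el[k] <- trimws(substr(lines[i + 3L + k], 32, 34))
    ba <- bb <- integer(nb); bo <- character(nb)
    for (k in seq_len(nb)) {
      ln <- lines[i + 3L + na + k]
      ba[k] <- as.integer(substr(ln, 1, 3))
      bb[k] <- as.integer(substr(ln, 4, 6))
      o <- as.integer(substr(ln, 7, 9))
      bo[k] <- if (o == 4L) "ar" else as.character(o)
    }
    j <- i + 3L + na + nb + 1L
    tt <- NA_real_
    while (j <= length(lines) && lines[j] != "$$$$") {
      if (grepl("^M  CHG", lines[j])) {
        flds <- scan(text = sub("^M  CHG\\s+\\d+", "", lines[j]),
                     quiet = TRUE)
        for (p in seq(1, length(flds), by = 2))
          chg[flds[p]] <- as.integer(flds[p + 1])
      }
      if (grepl("^>.*<tt>", lines[j], ignore.case = TRUE) && j < length(lines))
        tt <- suppressWarnings(as.numeric(lines[j + 1L]))
      j <- j + 1L
    }
    g <- new_molgraph(
      atoms = data.frame(element = el, charge = chg,
                         aromatic = rep(FALSE, na),
                         hcount = rep(NA_integer_, na),
                         stringsAsFactors = FALSE),
      bonds = data.frame(a = ba, b = bb, order = bo, stringsAsFactors = FALSE),
      name = name)
    g <- perceive_aromaticity(g)
    g <- assign_implicit_h(g)
    g <- normalize_nitro(g)
    validate_molgraph(g)
    recs[[length(recs) + 1L]] <- list(id = name, graph = g, tt = tt)
    i <- j + 1L
  }
  recs
}

#' The azolo[1,5-a]pyrimidine anticoagulant compound set
#'
#' Loads the packaged set of 23 tested azolo[1,5-a]pyrimidine derivatives and
#' condensed analogs plus three reference structures (dabigatran, dabigatran
#' etexilate, apixaban).  Structures were encoded from the published compound
#' names and schemes; salts (pyridinium, sodium, ammonium, morpholinium,
#' argininium) are stored as drawn and reduced to the parent ion by salt
#' stripping.  The thrombin-time activity column is a *reconstruction*: the
#' published table of absolute TT values is not machine-readable, so values
#' were rebuilt from the reported fold-changes over control (control fixed at
#' 30 s); see the packaged CSV and the methods vignette.
#'
#' @param include_references also return the reference drugs
#'   (default \code{FALSE}: the 23 tested compounds only).
#' @return a \code{compound_set} list (see [load_compound_set()]).
#' @export
paper_compounds <- function(include_references = FALSE) {
  path <- system.file("extdata", "azolopyrimidines_tt_synthetic.csv",
                      package = "azolopharm", mustWork = TRUE)
  set <- load_compound_set(path)
  if (!include_references) {
    refs <- c("dabigatran", "dabigatran_etexilate", "apixaban")
    set <- set[!vapply(set, function(cp) cp$id %in% refs, logical(1))]
    class(set) <- c("compound_set", "list")
  }
  set
}

#' @export
print.compound_set <- function(x, ...) {
  cat(sprintf("<compound_set: %d compounds, %d with activity>\n",
              length(x), sum(vapply(x, function(cp) !is.na(cp$tt), logical(1)))))
  invisible(x)
}

#' The published five-descriptor FIIa-inhibition pharmacophore
#'
#' The five QL descriptor types reported to carry sensitivity >= 1.1 for
#' thrombin (factor IIa) inhibition in the azolo[1,5-a]pyrimidine series,
#' with their reported sensitivity values.
#'
#' @return a \code{pharmacophore} object (see [extract_pharmacophore()]).
#' @export
reference_pharmacophore <- function() {
  d <- data.frame(
    label = c(ql_label("-N=", "CycAr06"), ql_label("-N=", "CycAr05"),
              ql_label("-N=", "=O"), ql_label("-N<", "=O"),
              ql_label("-CH3", ">C(<)")),
    sens = c(1.27, 1.23, 1.22, 1.10, 1.10),
    stringsAsFactors = FALSE)
  structure(list(descriptors = d[order(-d$sens), ], threshold = 1.1,
                 source = "published"),
            class = "pharmacophore")
}
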