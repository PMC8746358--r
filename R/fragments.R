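#' Structural fragment catalog
#'
#' The default catalog of simple electron-donor/acceptor fragments used as the
#' two halves of QL pair descriptors.  Each entry has a label, a documentation
#' pattern in SMARTS dialect, and a matcher.  The matchers operate on atom
#' environment features (element, hydrogen count, neighbor composition,
#' bond orders, aromaticity), which keeps matching deterministic and
#' atom-order invariant.
#'
#' Fragment semantics (after nitro normalization):
#' \describe{
#'   \item{NH2}{nitrogen with >= 2 hydrogens and only single bonds
#'     (primary amine / amide NH2).}
#'   \item{>NH}{nitrogen with exactly one hydrogen and two heavy neighbors,
#'     single/aromatic bonds only (secondary amine, lactam or pyrrole NH).}
#'   \item{-N<}{trivalent nitrogen, no hydrogens, three heavy neighbors,
#'     no double bond (tertiary amine, substituted amide or pyrrole-type
#'     ring nitrogen).}
#'   \item{-N=}{sp2 nitrogen: carries a double bond (imine, amidine, nitro)
#'     or is a two-connected aromatic ring nitrogen (pyridine-type).}
#'   \item{=O}{doubly bonded oxygen (C=O, N=O, S=O); the two geminal oxygens
#'     of a nitro or sulfone group form a single merged occurrence by
#'     default.}
#'   \item{-OH}{hydroxyl oxygen.}
#'   \item{-O-}{divalent ether oxygen, including aromatic ring oxygen.}
#'   \item{-SH, -S-}{thiol / divalent sulfur, including ring sulfur.}
#'   \item{-CH3}{methyl carbon.}
#'   \item{>C(<)}{branched sp3 carbon: no double/triple/aromatic bonds and
#'     at least two carbon neighbors.}
#'   \item{CN}{nitrile group (both atoms; the carbon is the path anchor).}
#'   \item{CycAr05, CycAr06}{aromatic ring of size 5 / 6; every ring atom is
#'     a path anchor.}
#'   \item{Hal}{halogen atom.}
#' }
#'
#' @param labels optional character vector restricting the catalog.
#' @param branch_rule neighbor rule for the branched-carbon fragment
#'   \code{>C(<)}: \code{"heavy2"} (sp3 carbon with >= 2 heavy neighbors of
#'   which >= 1 carbon, the calibrated default), \code{"carbon2"} (sp3 carbon
#'   with >= 2 carbon neighbors), or \code{"carbon3"} (any carbon with >= 3
#'   carbon neighbors).
#' @param merge_geminal_o treat two doubly-bonded oxygens on the same atom
#'   (nitro, sulfone) as a single acceptor occurrence spanning both oxygens
#'   (default \code{TRUE}; they are resonance-equivalent).
#' @return a data frame of class \code{fragment_catalog} with columns
#'   \code{label} and \code{pattern}; matchers are carried as an attribute.
#' @export
fragment_catalog <- function(labels = NULL,
                             branch_rule = c("heavy2", "carbon2", "carbon3"),
                             merge_geminal_o = TRUE) {
  branch_rule <- match.arg(branch_rule)
  branch_pattern <- switch(branch_rule,
    carbon2 = "[CX4]([#6])[#6]",
    heavy2  = "[CX4;!H3;!H4]([#6])[!#1]",
    carbon3 = "[#6]([#6])([#6])[#6]")
  defs <- list(
    list("NH2",    "[NX3;H2,H3;!$([N]=*)]",        match_n_h(2L)),
    list(">NH",    "[NX3;H1;D2]",                  match_n_h(1L)),
    list("-N<",    "[NX3;H0;D3;!$([N]=*)]",        match_n_tert),
    list("-N=",    "[$([NX2]),$([N]=*),$([nX2])]", match_n_sp2),
    list("=O",     "[OX1]=*",                      match_o_double(merge_geminal_o)),
    list("-OH",    "[OX2H1]",                      match_generic("O", h = 1L)),
    list("-O-",    "[OX2H0]",                      match_ether("O")),
    list("-SH",    "[SX2H1]",                      match_generic("S", h = 1L)),
    list("-S-",    "[SX2H0]",                      match_ether("S")),
    list("-CH3",   "[CH3,CH4]",                    match_ch3),
    list(">C(<)",  branch_pattern,                 match_c_branched(branch_rule)),
    list("CN",     "[CX2]#[NX1]",                  match_nitrile),
    list("CycAr05", "a1aaaa1",                     match_ring(5L)),
    list("CycAr06", "a1aaaaa1",                    match_ring(6L)),
    list("Hal",    "[F,Cl,Br,I]",                  match_halogen)
  )
  if (!is.null(labels)) {
    keep <- vapply(defs, function(d) d[[1]] %in% labels, logical(1))
    if (!all(labels %in% vapply(defs, `[[`, "", 1)))
      stop("unknown fragment label(s): ",
           paste(setdiff(labels, vapply(defs, `[[`, "", 1)), collapse = ", "))
    defs <- defs[keep]
  }
  if (length(defs) == 0L) stop("empty fragment catalog")
  cat_df <- data.frame(label = vapply(defs, `[[`, "", 1),
                       pattern = vapply(defs, `[[`, "", 2),
                       stringsAsFactors = FALSE)
  attr(cat_df, "matchers") <- lapply(defs, `[[`, 3)
  class(cat_df) <- c("fragment_catalog", "data.frame")
  cat_df
}

# ---- per-atom environment features -----------------------------------------

atom_features <- function(g) {
  n <- nrow(g$atoms)
  ord_num <- c("1" = 1L, "2" = 2L, "3" = 3L, "ar" = 1L)
  deg <- integer(n); ndbl <- integer(n); ntrp <- integer(n); nar <- integer(n)
  ncarbon <- integer(n)
  adj <- molgraph_adjacency(g)
  if (nrow(g$bonds) > 0) {
    for (k in seq_len(nrow(g$bonds))) {
      a <- g$bonds$a[k]; b <- g$bonds$b[k]; o <- g$bonds$order[k]
      deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L
      if (o == "2") { ndbl[a] <- ndbl[a] + 1L; ndbl[b] <- ndbl[b] + 1L }
      if (o == "3") { ntrp[a] <- ntrp[a] + 1L; ntrp[b] <- ntrp[b] + 1L }
      if (o == "ar") { nar[a] <- nar[a] + 1L; nar[b] <- nar[b] + 1L }
      if (g$atoms$element[b] == "C") ncarbon[a] <- ncarbon[a] + 1L
      if (g$atoms$element[a] == "C") ncarbon[b] <- ncarbon[b] + 1L
    }
  }
  list(el = g$atoms$element, h = g$atoms$hcount, chg = g$atoms$charge,
       ar = g$atoms$aromatic, deg = deg, ndbl = ndbl, ntrp = ntrp,
       nar = nar, ncarbon = ncarbon, adj = adj)
}

# ---- matchers: each returns a list of occurrences --------------------------
# an occurrence is list(atoms = <matched atom set>, anchors = <path endpoints>)

occ <- function(atoms, anchors = atoms) list(atoms = atoms, anchors = anchors)

match_n_h <- function(hmin) function(g, ft) {
  idx <- which(ft$el == "N" & ft$h >= hmin & ft$h <= (if (hmin == 2L) 3L else hmin) &
               ft$ndbl == 0L & ft$ntrp == 0L)
  lapply(idx, occ)
}

match_n_tert <- function(g, ft) {
  idx <- which(ft$el == "N" & ft$h == 0L & ft$deg == 3L &
               ft$ndbl == 0L & ft$ntrp == 0L)
  lapply(idx, occ)
}

match_n_sp2 <- function(g, ft) {
  idx <- which(ft$el == "N" & ft$ntrp == 0L &
               (ft$ndbl > 0L | (ft$ar & ft$deg == 2L & ft$h == 0L)))
  lapply(idx, occ)
}

match_o_double <- function(merge) function(g, ft) {
  idx <- which(ft$el == "O" & ft$ndbl >= 1L & ft$deg == 1L)
  if (!merge || length(idx) < 2L) return(lapply(idx, occ))
  # group by the atom each =O is attached to: nitro / sulfone oxygens are
  # resonance-equivalent and form one acceptor site
  attached <- vapply(idx, function(i) ft$adj[[i]][1], 0L)
  out <- list()
  for (a in unique(attached)) {
    os <- idx[attached == a]
    out[[length(out) + 1L]] <- occ(atoms = sort(os), anchors = sort(os))
  }
  out
}

match_generic <- function(element, h) function(g, ft) {
  idx <- which(ft$el == element & ft$h == h & ft$ndbl == 0L & ft$ntrp == 0L)
  lapply(idx, occ)
}

match_ch3 <- function(g, ft) {
  idx <- which(ft$el == "C" & ft$h >= 3L & ft$ndbl == 0L & ft$ntrp == 0L)
  lapply(idx, occ)
}

match_ether <- function(element) function(g, ft) {
  idx <- which(ft$el == element & ft$h == 0L & ft$deg == 2L &
               ft$ndbl == 0L & ft$ntrp == 0L)
  lapply(idx, occ)
}

match_c_branched <- function(rule) function(g, ft) {
  sp3 <- ft$el == "C" & !ft$ar & ft$ndbl == 0L & ft$ntrp == 0L & ft$nar == 0L
  idx <- switch(rule,
    carbon2 = which(sp3 & ft$ncarbon >= 2L),
    heavy2  = which(sp3 & ft$deg >= 2L & ft$ncarbon >= 1L),
    carbon3 = which(ft$el == "C" & ft$ncarbon >= 3L))
  lapply(idx, occ)
}

match_nitrile <- function(g, ft) {
  out <- list()
  for (k in seq_len(nrow(g$bonds))) {
    if (g$bonds$order[k] != "3") next
    a <- g$bonds$a[k]; b <- g$bonds$b[k]
    cn <- NULL
    if (ft$el[a] == "C" && ft$el[b] == "N") cn <- c(a, b)
    if (ft$el[b] == "C" && ft$el[a] == "N") cn <- c(b, a)
    if (!is.null(cn) && ft$deg[cn[2]] == 1L)
      out[[length(out) + 1L]] <- occ(atoms = cn, anchors = cn[1])
  }
  out
}

match_ring <- function(size) function(g, ft) {
  rings <- molgraph_rings(g, 6L)
  out <- list()
  for (r in rings) {
    if (length(r) != size) next
    if (!all(ft$ar[r])) next
    # every ring bond aromatic
    ok <- TRUE
    for (i in seq_along(r)) {
      v <- r[i]; w <- r[if (i == length(r)) 1 else i + 1]
      k <- which((g$bonds$a == v & g$bonds$b == w) | (g$bonds$a == w & g$bonds$b == v))[1]
      if (g$bonds$order[k] != "ar") { ok <- FALSE; break }
    }
    if (ok) out[[length(out) + 1L]] <- occ(sort(r))
  }
  out
}

match_halogen <- function(g, ft) {
  idx <- which(ft$el %in% c("F", "Cl", "Br", "I"))
  lapply(idx, occ)
}

#' Match catalog fragments in a molecule
#'
#' Finds every occurrence of every catalog fragment.  Occurrences of
#' different fragments may overlap; duplicate occurrences of the same
#' fragment (identical matched atom set) are reported once.
#'
#' @param mol a normalized [molgraph] (salt-stripped, aromaticity perceived).
#' @param catalog a [fragment_catalog].
#' @return a data-frame-backed list: one element per occurrence with
#'   \code{label}, \code{atoms} (matched set) and \code{anchors}
#'   (path endpoints).
#' @examples
#' match_fragments(parse_smiles("c1ccoc1"), fragment_catalog())
#' @export
match_fragments <- function(mol, catalog = fragment_catalog()) {
  if (!inherits(catalog, "fragment_catalog") || nrow(catalog) == 0L)
    stop("empty or invalid fragment catalog")
  ft <- atom_features(mol)
  matchers <- attr(catalog, "matchers")
  out <- list()
  for (i in seq_len(nrow(catalog))) {
    hits <- matchers[[i]](mol, ft)
    seen <- character(0)
    for (h in hits) {
      key <- paste(sort(h$atoms), collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- list(label = catalog$label[i],
                                      atoms = sort(h$atoms),
                                      anchors = h$anchors)
    }
  }
  out
}
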