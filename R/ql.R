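#' Carbon-chain path test
#'
#' Tests whether two atoms are connected by at least one simple path whose
#' intermediate atoms are all carbon (aromatic or aliphatic).  A direct bond
#' (zero intermediates) satisfies the condition vacuously, so directly bonded
#' donor/acceptor pairs such as the two halves of a nitro group qualify.
#'
#' @param mol a [molgraph].
#' @param a,b distinct atom indices.
#' @param max_intermediates maximum number of intermediate atoms allowed
#'   (default \code{Inf}).
#' @param exclude atom indices that may not be used as intermediates.
#' @return logical.
#' @examples
#' m <- parse_smiles("NCCO")               # ethanolamine
#' carbon_path_exists(m, 1, 4)             # TRUE: N-C-C-O
#' @export
carbon_path_exists <- function(mol, a, b, max_intermediates = Inf,
                               exclude = integer(0)) {
  n <- nrow(mol$atoms)
  if (a == b || a < 1 || b < 1 || a > n || b > n) stop("invalid atom indices")
  adj <- molgraph_adjacency(mol)
  if (b %in% adj[[a]]) return(TRUE)
  if (max_intermediates < 1) return(FALSE)
  allowed <- mol$atoms$element == "C"
  allowed[c(a, b)] <- FALSE
  allowed[exclude] <- FALSE
  # BFS from a through allowed carbons; count of intermediates = depth
  dist <- rep(NA_integer_, n)
  queue <- intersect(adj[[a]], which(allowed))
  dist[queue] <- 1L
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    if (b %in% adj[[v]]) return(TRUE)
    if (dist[v] >= max_intermediates) next
    for (w in adj[[v]]) {
      if (allowed[w] && is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
  }
  FALSE
}

#' QL pair-descriptor enumeration rules
#'
#' Collects the tunable matching conventions of the QL descriptor engine.
#' The shipped defaults were calibrated so that the five-descriptor
#' thrombin-inhibition pharmacophore reproduces the published entry counts on
#' the reference compounds; see the methods vignette for the calibration.
#'
#' @param max_intermediates maximum number of intermediate (carbon) atoms on
#'   the connecting path.
#' @param ring_self_pairing may an atom fragment pair with an aromatic ring
#'   fragment that contains it (e.g. a pyridine-type nitrogen with its own
#'   ring)?  Default \code{TRUE}.
#' @param ring_label_dedup if \code{TRUE} (default), a given aromatic ring
#'   occurrence contributes at most one entry per descriptor: multiple
#'   partners of the same fragment type pairing with the same ring collapse
#'   to a single entry (the ring is one binding feature).
#' @param dedupe_by_union if \code{TRUE}, two occurrence pairs of the same
#'   descriptor that cover the identical union of atoms count once.  Default
#'   \code{FALSE}.
#' @return a list of class \code{ql_rules}.
#' @export
ql_rules <- function(max_intermediates = Inf,
                     ring_self_pairing = TRUE,
                     ring_label_dedup = TRUE,
                     dedupe_by_union = FALSE) {
  structure(list(max_intermediates = max_intermediates,
                 ring_self_pairing = ring_self_pairing,
                 ring_label_dedup = ring_label_dedup,
                 dedupe_by_union = dedupe_by_union),
            class = "ql_rules")
}

#' Enumerate QL descriptors of a molecule
#'
#' A QL descriptor is an unordered pair of structural fragments
#' \code{\{A ... B\}} whose occurrences have disjoint matched atom sets and
#' whose anchor atoms are joined by a path passing only through carbon atoms.
#' Every qualifying occurrence pair increments the descriptor count; pairs of
#' two occurrences of the same fragment label are allowed.
#'
#' @param mol a normalized [molgraph].
#' @param catalog a [fragment_catalog].
#' @param rules a [ql_rules] object.
#' @return named integer vector: descriptor label (\code{"{A ... B}"},
#'   labels in sorted order) to occurrence-pair count.
#' @examples
#' enumerate_ql_descriptors(parse_smiles("Nc1ccc(O)cc1"))  # 4-aminophenol
#' @export
enumerate_ql_descriptors <- function(mol, catalog = fragment_catalog(),
                                     rules = ql_rules()) {
  occs <- match_fragments(mol, catalog)
  count_ql_pairs(mol, occs, rules)
}

# shared pair-counting core, operating on a precomputed occurrence list
count_ql_pairs <- function(mol, occs, rules) {
  counts <- integer(0)
  if (length(occs) < 2L) return(counts)
  seen <- character(0)   # dedup keys already counted
  is_ring <- vapply(occs, function(o) grepl("^CycAr", o$label), logical(1))
  for (i in seq_len(length(occs) - 1L)) {
    for (j in (i + 1L):length(occs)) {
      oi <- occs[[i]]; oj <- occs[[j]]
      inter <- intersect(oi$atoms, oj$atoms)
      contained <- length(inter) > 0L &&
        (all(oi$atoms %in% oj$atoms) || all(oj$atoms %in% oi$atoms))
      if (length(inter) > 0L && (!contained || !rules$ring_self_pairing)) next
      hit <- contained
      if (!hit) {
        excl <- union(oi$atoms, oj$atoms)
        for (a in oi$anchors) {
          for (b in oj$anchors) {
            if (a == b) next
            if (carbon_path_exists(mol, a, b,
                                   max_intermediates = rules$max_intermediates,
                                   exclude = setdiff(excl, c(a, b)))) {
              hit <- TRUE; break
            }
          }
          if (hit) break
        }
      }
      if (!hit) next
      lab <- ql_label(oi$label, oj$label)
      key <- NULL
      if (rules$ring_label_dedup && (is_ring[i] || is_ring[j])) {
        ring_atoms <- c(if (is_ring[i]) oi$atoms, if (is_ring[j]) oj$atoms)
        key <- paste0(lab, "|R|", paste(sort(ring_atoms), collapse = ","))
      } else if (rules$dedupe_by_union) {
        key <- paste0(lab, "|U|",
                      paste(sort(union(oi$atoms, oj$atoms)), collapse = ","))
      }
      if (!is.null(key)) {
        if (key %in% seen) next
        seen <- c(seen, key)
      }
      counts[lab] <- (if (lab %in% names(counts)) counts[[lab]] else 0L) + 1L
    }
  }
  counts[order(names(counts))]
}

#' Render a QL descriptor label
#'
#' @param a,b fragment labels; order-insensitive.
#' @return the canonical rendering \code{"\{A ... B\}"} with labels sorted.
#' @export
ql_label <- function(a, b) {
  p <- sort(c(a, b))
  sprintf("{%s ... %s}", p[1], p[2])
}
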