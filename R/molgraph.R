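#' Molecular graph objects
#'
#' A \code{molgraph} is a light-weight molecular graph: a data frame of atoms
#' (\code{element}, \code{charge}, \code{aromatic}, \code{hcount}) and a data
#' frame of bonds (\code{a}, \code{b}, \code{order} with order one of
#' \code{"1"}, \code{"2"}, \code{"3"}, \code{"ar"}), plus a name.  It is the
#' substrate for fragment matching and QL descriptor enumeration.
#'
#' @param atoms,bonds data frames as described above.
#' @param name identifier string.
#' @return an object of class \code{molgraph}.
#' @export
new_molgraph <- function(atoms, bonds, name = "") {
  structure(list(atoms = atoms, bonds = bonds, name = name),
            class = "molgraph")
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph%s: %d atoms, %d bonds, formula %s>\n",
              if (nzchar(x$name)) paste0(" ", x$name) else "",
              nrow(x$atoms), nrow(x$bonds), molgraph_formula(x)))
  invisible(x)
}

#' @export
format.molgraph <- function(x, ...) molgraph_formula(x)

#' Heavy-atom molecular formula (Hill order, implicit H included)
#' @param g a [molgraph].
#' @return a string such as \code{"C9H5N5O4"}.
#' @export
molgraph_formula <- function(g) {
  cnt <- table(g$atoms$element)
  h <- sum(g$atoms$hcount)
  parts <- character(0)
  fmt <- function(e, k) if (k == 1) e else paste0(e, k)
  if ("C" %in% names(cnt)) parts <- c(parts, fmt("C", cnt[["C"]]))
  if (h > 0) parts <- c(parts, fmt("H", h))
  rest <- sort(setdiff(names(cnt), c("C", "H")))
  for (e in rest) parts <- c(parts, fmt(e, cnt[[e]]))
  paste(parts, collapse = "")
}

validate_molgraph <- function(g) {
  n <- nrow(g$atoms)
  if (n == 0L) stop("molgraph has no atoms")
  if (nrow(g$bonds) > 0) {
    if (any(g$bonds$a < 1L | g$bonds$a > n | g$bonds$b < 1L | g$bonds$b > n))
      stop("bond endpoint out of range")
    if (any(g$bonds$a == g$bonds$b)) stop("self-bond in molgraph")
    if (!all(g$bonds$order %in% c("1", "2", "3", "ar")))
      stop("invalid bond order")
  }
  if (any(g$atoms$hcount < 0L, na.rm = TRUE))
    stop("negative implicit hydrogen count")
  invisible(g)
}

# adjacency list (cached on the object attribute)
molgraph_adjacency <- function(g) {
  cached <- attr(g, "adjacency")
  if (!is.null(cached) && length(cached) == nrow(g$atoms)) return(cached)
  n <- nrow(g$atoms)
  adj <- vector("list", n)
  if (nrow(g$bonds) > 0) {
    for (k in seq_len(nrow(g$bonds))) {
      a <- g$bonds$a[k]; b <- g$bonds$b[k]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  adj
}

# connected components; returns integer vector of component ids
molgraph_components <- function(g) {
  n <- nrow(g$atoms)
  adj <- molgraph_adjacency(g)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
    }
  }
  comp
}

# induced subgraph on a set of atom indices (renumbered)
molgraph_subgraph <- function(g, keep) {
  keep <- sort(unique(keep))
  map <- integer(nrow(g$atoms)); map[keep] <- seq_along(keep)
  sel <- g$bonds$a %in% keep & g$bonds$b %in% keep
  b <- g$bonds[sel, , drop = FALSE]
  b$a <- map[b$a]; b$b <- map[b$b]
  rownames(b) <- NULL
  at <- g$atoms[keep, , drop = FALSE]
  rownames(at) <- NULL
  new_molgraph(at, b, g$name)
}

#' Enumerate small rings
#'
#' Returns all simple cycles of length 3 to \code{max_size} as a list of atom
#' index vectors, deduplicated by atom set.  Exhaustive for the ring sizes the
#' fragment catalog uses (aromatic 5- and 6-rings), including every ring of a
#' fused system.
#'
#' @param g a [molgraph].
#' @param max_size largest ring size to report (default 6).
#' @return list of integer vectors (ring atoms, in ring order).
#' @export
molgraph_rings <- function(g, max_size = 6L) {
  adj <- molgraph_adjacency(g)
  n <- nrow(g$atoms)
  found <- list(); seen <- character(0)
  for (start in seq_len(n)) {
    # DFS paths starting at 'start' using only atoms >= start
    stack <- list(start)
    while (length(stack) > 0) {
      path <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      v <- path[length(path)]
      for (w in adj[[v]]) {
        if (w == start && length(path) >= 3L) {
          key <- paste(sort(path), collapse = ",")
          if (!key %in% seen) { seen <- c(seen, key); found[[length(found) + 1L]] <- path }
        } else if (w > start && !w %in% path && length(path) < max_size) {
          stack[[length(stack) + 1L]] <- c(path, w)
        }
      }
    }
  }
  found
}

#' Perceive aromaticity of Kekule-drawn rings
#'
#' Per-ring test on all rings of size 5 or 6: each ring atom must be sp2
#' (carry an in-ring double bond, an exocyclic double bond to O/N/S, be
#' already flagged aromatic, or be a heteroatom with only single bonds), and
#' the Huckel electron count over the ring must equal 6.  Carbons with an
#' exocyclic double bond contribute 0 electrons (pyridinone-type rings are
#' therefore aromatic), atoms with an in-ring double bond contribute 1, and
#' single-bonded heteroatoms contribute their lone pair (2).  Atoms and bonds
#' of qualifying rings are flagged aromatic.  Flags already present in the
#' input are never removed.
#'
#' @param g a [molgraph].
#' @return the graph with updated aromatic flags.
#' @export
perceive_aromaticity <- function(g) {
  rings <- molgraph_rings(g, 6L)
  rings <- rings[lengths(rings) >= 5L]
  if (length(rings) == 0L) return(g)
  bond_ix <- function(a, b)
    which((g$bonds$a == a & g$bonds$b == b) | (g$bonds$a == b & g$bonds$b == a))[1]
  adj <- molgraph_adjacency(g)
  for (ring in rings) {
    k <- length(ring)
    electrons <- 0L; ok <- TRUE
    for (idx in seq_len(k)) {
      v <- ring[idx]
      nb_in <- c(ring[if (idx == 1) k else idx - 1], ring[if (idx == k) 1 else idx + 1])
      ords_in <- vapply(nb_in, function(w) g$bonds$order[bond_ix(v, w)], "")
      nb_out <- setdiff(adj[[v]], nb_in)
      ords_out <- vapply(nb_out, function(w) g$bonds$order[bond_ix(v, w)], "")
      el <- g$atoms$element[v]
      if (any(ords_in == "2") || any(ords_in == "ar")) {
        electrons <- electrons + 1L
      } else if (any(ords_out == "2")) {
        # exocyclic double bond (carbonyl-type): contributes no pi electrons
        electrons <- electrons + 0L
      } else if (el %in% c("N", "O", "S", "P") || (el == "C" && g$atoms$charge[v] == -1L)) {
        electrons <- electrons + 2L
      } else { ok <- FALSE; break }
      if (any(ords_out == "3") || any(ords_in == "3")) { ok <- FALSE; break }
    }
    if (ok && electrons == 6L) {
      g$atoms$aromatic[ring] <- TRUE
      for (idx in seq_len(length(ring))) {
        v <- ring[idx]; w <- ring[if (idx == length(ring)) 1 else idx + 1]
        bi <- bond_ix(v, w)
        if (g$bonds$order[bi] %in% c("1", "2")) g$bonds$order[bi] <- "ar"
      }
    }
  }
  attr(g, "adjacency") <- NULL
  g
}

#' Strip counterions, keeping the parent component
#'
#' Reduces a multi-component structure (a salt) to its parent organic
#' component: the largest component that contains a heteroatom.  Size is heavy
#' atom count; ties are broken deterministically by the lexicographically
#' smallest canonical signature (and flagged with a warning, since the choice
#' is then conventional).  A single-component input is returned unchanged.
#'
#' @param mol a [molgraph].
#' @return a single-component [molgraph].
#' @export
strip_counterions <- function(mol) {
  if (nrow(mol$atoms) == 0L) stop("empty molecular graph")
  comp <- molgraph_components(mol)
  if (max(comp) == 1L) return(mol)
  sizes <- tabulate(comp)
  hetero <- vapply(seq_len(max(comp)), function(ci)
    any(!mol$atoms$element[comp == ci] %in% c("C", "H")), logical(1))
  cand <- which(hetero)
  if (length(cand) == 0L) cand <- seq_len(max(comp))
  best_size <- max(sizes[cand])
  cand <- cand[sizes[cand] == best_size]
  if (length(cand) > 1L) {
    sigs <- vapply(cand, function(ci)
      component_signature(mol, which(comp == ci)), "")
    if (anyDuplicated(sigs) || length(unique(sigs)) > 1L)
      warning("equal-size components in salt; tie broken by canonical signature")
    cand <- cand[order(sigs)][1]
  }
  molgraph_subgraph(mol, which(comp == cand[1]))
}

#' Neutralize a salt-stripped parent ion
#'
#' Converts the common anionic/cationic sites of a stripped parent back to
#' the neutral acid/base form: deprotonated ring or amide nitrogens
#' (\code{[n-]}, \code{[N-]}) and alkoxide/phenolate oxygens gain a proton;
#' protonated amines lose one.  Charge-separated groups that are inherently
#' zwitterionic within one valence unit (normalized nitro has already been
#' rewritten) are left alone.  This puts all salts of the same NH acid on a
#' single uniform protonation state before descriptor generation.
#'
#' @param mol a [molgraph].
#' @return the neutralized graph.
#' @export
neutralize_parent <- function(mol) {
  ft <- atom_features(mol)
  for (i in seq_len(nrow(mol$atoms))) {
    el <- mol$atoms$element[i]; chg <- mol$atoms$charge[i]
    if (chg == -1L && el == "N") {
      mol$atoms$charge[i] <- 0L
      mol$atoms$hcount[i] <- mol$atoms$hcount[i] + 1L
    } else if (chg == -1L && el == "O" && ft$ndbl[i] == 0L && ft$deg[i] == 1L) {
      mol$atoms$charge[i] <- 0L
      mol$atoms$hcount[i] <- 1L
    } else if (chg == 1L && el == "N" && mol$atoms$hcount[i] >= 1L) {
      mol$atoms$charge[i] <- 0L
      mol$atoms$hcount[i] <- mol$atoms$hcount[i] - 1L
    }
  }
  mol
}

# order-invariant signature of a component: sorted atom descriptors plus
# sorted canonical edge labels
component_signature <- function(g, atoms_idx) {
  sub <- molgraph_subgraph(g, atoms_idx)
  a <- sub$atoms
  alab <- sort(paste0(a$element, "/", a$charge, "/", as.integer(a$aromatic),
                      "/", a$hcount))
  deg <- integer(nrow(a))
  for (k in seq_len(nrow(sub$bonds))) {
    deg[sub$bonds$a[k]] <- deg[sub$bonds$a[k]] + 1L
    deg[sub$bonds$b[k]] <- deg[sub$bonds$b[k]] + 1L
  }
  elab <- character(0)
  if (nrow(sub$bonds) > 0) {
    ends <- cbind(paste0(a$element[sub$bonds$a], deg[sub$bonds$a]),
                  paste0(a$element[sub$bonds$b], deg[sub$bonds$b]))
    elab <- sort(paste0(pmin(ends[, 1], ends[, 2]), "~",
                        pmax(ends[, 1], ends[, 2]), "~", sub$bonds$order))
  }
  paste(c(alab, "|", elab), collapse = ";")
}
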