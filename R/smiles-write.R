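#' Write a molecular graph as a SMILES string
#'
#' Serializes a [molgraph] back to SMILES.  Aromatic atoms are written in
#' lowercase with aromatic ring bonds implicit; the output is not canonical
#' but re-parses to an isomorphic graph (round-trip stability).  An optional
#' atom ordering permutes the DFS start/neighbor order, which is used by the
#' atom-order-invariance tests.
#'
#' @param g a [molgraph].
#' @param order optional permutation of atom indices controlling traversal
#'   priority (default: input order).
#' @return a SMILES string.
#' @export
write_smiles <- function(g, order = NULL) {
  n <- nrow(g$atoms)
  if (is.null(order)) order <- seq_len(n)
  stopifnot(length(order) == n)
  prio <- integer(n); prio[order] <- seq_len(n)
  adj <- molgraph_adjacency(g)
  bond_ord <- function(a, b) {
    k <- which((g$bonds$a == a & g$bonds$b == b) | (g$bonds$a == b & g$bonds$b == a))[1]
    g$bonds$order[k]
  }
  bond_sym <- function(o, a, b) {
    switch(o,
           "1" = if (g$atoms$aromatic[a] && g$atoms$aromatic[b]) "-" else "",
           "2" = "=", "3" = "#",
           "ar" = "")
  }
  # would a plain (bracket-free) token reproduce this atom's H count?
  implicit_h_ok <- function(i) {
    ord_num <- c("1" = 1L, "2" = 2L, "3" = 3L, "ar" = 1L)
    ks <- which(g$bonds$a == i | g$bonds$b == i)
    s <- if (length(ks)) sum(ord_num[g$bonds$order[ks]]) else 0L
    multi <- any(g$bonds$order[ks] %in% c("2", "3"))
    used <- s + (if (g$atoms$aromatic[i] && !multi) 1L else 0L)
    v <- .charged_valence(g$atoms$element[i], 0L)
    v <- v[v >= used]
    h <- if (length(v) == 0L) 0L else max(0L, min(v) - used)
    h == g$atoms$hcount[i]
  }
  atom_token <- function(i) {
    el <- g$atoms$element[i]
    sym <- if (g$atoms$aromatic[i]) tolower(el) else el
    plain_ok <- g$atoms$charge[i] == 0L &&
      el %in% c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I") &&
      implicit_h_ok(i)
    if (plain_ok) return(sym)
    h <- g$atoms$hcount[i]; chg <- g$atoms$charge[i]
    hs <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
    cs <- if (chg == 0L) "" else if (chg == 1L) "+" else if (chg == -1L) "-"
          else sprintf("%+d", chg)
    paste0("[", sym, hs, cs, "]")
  }

  # ---- pass 1: DFS forest, classify tree vs ring (back) edges --------------
  visited <- logical(n)
  parent <- integer(n)
  back_edges <- list()       # list of c(a, b) with a deeper, b shallower
  dfs_order <- integer(0)
  for (root in order) {
    if (visited[root]) next
    stack <- list(c(root, 0L))
    while (length(stack) > 0) {
      fr <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      v <- fr[1]; p <- fr[2]
      if (visited[v]) next
      visited[v] <- TRUE; parent[v] <- p
      dfs_order <- c(dfs_order, v)
      nbs <- adj[[v]][order(prio[adj[[v]]])]
      for (w in rev(nbs)) {
        if (w == p) next
        if (visited[w]) {
          key <- paste(min(v, w), max(v, w))
          if (!key %in% vapply(back_edges, function(e) paste(min(e), max(e)), ""))
            back_edges[[length(back_edges) + 1L]] <- c(v, w)
        } else stack[[length(stack) + 1L]] <- c(w, v)
      }
    }
  }
  # assign ring-closure labels to both endpoints of each back edge
  clos <- vector("list", n)
  for (k in seq_along(back_edges)) {
    e <- back_edges[[k]]
    lbl <- if (k < 10) as.character(k) else paste0("%", sprintf("%02d", k))
    o <- bond_ord(e[1], e[2])
    tok <- paste0(bond_sym(o, e[1], e[2]), lbl)
    clos[[e[1]]] <- c(clos[[e[1]]], tok)
    clos[[e[2]]] <- c(clos[[e[2]]], tok)
  }
  # children in the DFS tree, in priority order
  kids <- vector("list", n)
  for (v in dfs_order) if (parent[v] > 0L)
    kids[[parent[v]]] <- c(kids[[parent[v]]], v)

  # ---- pass 2: emit -------------------------------------------------------
  emit_sub <- function(v) {
    out <- atom_token(v)
    for (tok in clos[[v]]) out <- paste0(out, tok)
    ch <- kids[[v]]
    if (length(ch) > 0) {
      for (ki in seq_along(ch)) {
        w <- ch[ki]
        o <- bond_ord(v, w)
        piece <- paste0(bond_sym(o, v, w), emit_sub(w))
        out <- if (ki < length(ch)) paste0(out, "(", piece, ")")
               else paste0(out, piece)
      }
    }
    out
  }
  roots <- dfs_order[parent[dfs_order] == 0L]
  paste(vapply(roots, emit_sub, ""), collapse = ".")
}
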