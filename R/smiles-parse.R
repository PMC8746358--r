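#' Parse a SMILES string into a molecular graph
#'
#' Builds a [molgraph] from a SMILES string.  The supported dialect covers
#' organic-subset atoms (\code{B C N O P S F Cl Br I}), aromatic lowercase
#' atoms, bracket atoms with explicit hydrogen counts and formal charges
#' (stereo markers are accepted and ignored), bond symbols \code{- = # :},
#' branches, two-digit and \code{\%nn} ring closures, and dot-separated
#' components.  Aromatic flags present in the input are taken as authoritative;
#' in addition, rings drawn in Kekule form are aromatized by a per-ring
#' sp2/electron-count rule (see [perceive_aromaticity]), so e.g.
#' \code{C1=CC=CC=C1} and \code{c1ccccc1} give the same graph.
#'
#' Nitro groups written in the charge-separated form
#' \code{[N+](=O)[O-]} are normalized to the uncharged pentavalent form with
#' two N=O double bonds, so that both oxygens present identical
#' acceptor fragments; set \code{normalize = FALSE} to keep the input form.
#'
#' @param text a single SMILES string.
#' @param name optional identifier stored in the graph.
#' @param normalize logical; normalize charge-separated nitro groups
#'   (default \code{TRUE}).
#' @return a [molgraph] object.
#' @examples
#' furan <- parse_smiles("c1ccoc1")
#' sum(furan$atoms$aromatic)  # 5
#' @export
parse_smiles <- function(text, name = NULL, normalize = TRUE) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("'text' must be a single SMILES string")
  if (!nzchar(text)) stop("empty SMILES string")

  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)

  el <- character(0); arom <- logical(0); chg <- integer(0)
  hexp <- integer(0)  # NA_integer_ = implicit
  b_a <- integer(0); b_b <- integer(0); b_o <- character(0)

  prev <- NA_integer_          # previous atom index
  stack <- integer(0)          # branch stack
  pending <- ""                # pending bond symbol
  ring <- list()               # closure digit -> list(atom, sym)

  fail <- function(msg, pos) {
    stop(sprintf("SMILES parse error at position %d ('%s'): %s",
                 pos, substr(text, pos, pos), msg), call. = FALSE)
  }

  add_atom <- function(sym, aromatic, charge, h) {
    el[length(el) + 1L] <<- sym
    arom[length(arom) + 1L] <<- aromatic
    chg[length(chg) + 1L] <<- charge
    hexp[length(hexp) + 1L] <<- h
    idx <- length(el)
    if (!is.na(prev)) {
      o <- pending
      if (o == "") o <- if (arom[prev] && aromatic) "ar" else "1"
      b_a[length(b_a) + 1L] <<- prev
      b_b[length(b_b) + 1L] <<- idx
      b_o[length(b_o) + 1L] <<- o
    }
    pending <<- ""
    prev <<- idx
    idx
  }

  close_ring <- function(digit, pos) {
    if (is.na(prev)) fail("ring closure before any atom", pos)
    key <- as.character(digit)
    if (is.null(ring[[key]])) {
      ring[[key]] <<- list(atom = prev, sym = pending)
      pending <<- ""
    } else {
      open <- ring[[key]]
      ring[[key]] <<- NULL
      o <- if (nzchar(pending)) pending else open$sym
      if (o == "") o <- if (arom[open$atom] && arom[prev]) "ar" else "1"
      if (open$atom == prev) fail("ring bond to self", pos)
      b_a[length(b_a) + 1L] <<- open$atom
      b_b[length(b_b) + 1L] <<- prev
      b_o[length(b_o) + 1L] <<- o
      pending <<- ""
    }
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("-", "=", "#", ":")) {
      pending <- switch(ch, "-" = "1", "=" = "2", "#" = "3", ":" = "ar")
      i <- i + 1L
    } else if (ch %in% c("/", "\\")) {       # cis/trans markers: plain single
      pending <- "1"
      i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) fail("branch before any atom", i)
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) fail("unmatched ')'", i)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") {
      prev <- NA_integer_; pending <- ""; i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch, i); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", paste0(chars[i + 1L], chars[i + 2L])))
        fail("'%' must be followed by two digits", i)
      close_ring(paste0(chars[i + 1L], chars[i + 2L]), i)
      i <- i + 3L
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) fail("unterminated bracket atom", i)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Za-z][a-z]?)(@{0,2})(H[0-9]*)?([+-][0-9]*|[+]+|[-]+)?$",
        body))[[1]]
      if (length(m) == 0L) fail(sprintf("cannot parse bracket atom '[%s]'", body), i)
      sym <- m[3]
      aromatic <- sym %in% c("b", "c", "n", "o", "p", "s", "se", "as")
      elem <- if (aromatic) {
        paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, nchar(sym)))
      } else sym
      if (!elem %in% names(.default_valence))
        fail(sprintf("unknown element '%s'", elem), i)
      h <- 0L
      if (!is.na(m[5]) && nzchar(m[5]))
        h <- if (m[5] == "H") 1L else as.integer(sub("H", "", m[5]))
      charge <- 0L
      if (!is.na(m[6]) && nzchar(m[6])) {
        cs <- m[6]
        charge <- if (grepl("^[+-][0-9]+$", cs)) {
          as.integer(cs)
        } else {
          sum(ifelse(strsplit(cs, "")[[1]] == "+", 1L, -1L))
        }
      }
      add_atom(elem, aromatic, charge, h)
      i <- j + 1L
    } else if (grepl("[A-Za-z*]", ch)) {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(two, FALSE, 0L, NA_integer_); i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        add_atom(ch, FALSE, 0L, NA_integer_); i <- i + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        add_atom(toupper(ch), TRUE, 0L, NA_integer_); i <- i + 1L
      } else fail("unexpected atom symbol", i)
    } else if (ch == " ") {
      break  # SMILES title/comment field
    } else fail("unexpected character", i)
  }
  if (length(stack) > 0L) stop("SMILES parse error: unmatched '('", call. = FALSE)
  if (length(ring) > 0L)
    stop(sprintf("SMILES parse error: unclosed ring bond(s): %s",
                 paste(names(ring), collapse = ", ")), call. = FALSE)
  if (length(el) == 0L) stop("SMILES parse error: no atoms", call. = FALSE)

  g <- new_molgraph(
    atoms = data.frame(element = el, charge = chg, aromatic = arom,
                       hcount = hexp, stringsAsFactors = FALSE),
    bonds = data.frame(a = b_a, b = b_b, order = b_o, stringsAsFactors = FALSE),
    name = if (is.null(name)) "" else as.character(name))
  g <- perceive_aromaticity(g)
  g <- assign_implicit_h(g)
  if (normalize) g <- normalize_nitro(g)
  validate_molgraph(g)
  g
}

# standard/default valences used for implicit hydrogen assignment
.default_valence <- list(
  B = 3L, C = 4L, N = 3L, O = 2L, P = c(3L, 5L), S = c(2L, 4L, 6L),
  F = 1L, Cl = 1L, Br = 1L, I = 1L,
  Na = 0L, K = 0L, Li = 0L, Ca = 0L, Mg = 0L, Fe = 0L, Se = 2L, Si = 4L)

# effective valence after charge: N+ -> 4, N- -> 2, O- -> 1 etc.
.charged_valence <- function(element, charge) {
  v <- .default_valence[[element]]
  if (charge == 0L || is.null(v)) return(v)
  if (element == "N") return(max(0L, 3L + charge))
  if (element == "O") return(max(0L, 2L + charge))
  if (element == "C") return(if (charge != 0L) 3L else 4L)
  if (element == "S") return(max(0L, 2L + charge))
  if (element %in% c("Na", "K", "Li")) return(0L)
  v
}

# Assign implicit hydrogen counts to atoms that did not carry an explicit
# H specification.  Aromatic atoms receive a +1 valence increment for the
# delocalized pi bond unless they already carry a double/triple bond.
assign_implicit_h <- function(g) {
  ord_num <- c("1" = 1L, "2" = 2L, "3" = 3L, "ar" = 1L)
  nb_sum <- integer(nrow(g$atoms))
  has_multi <- logical(nrow(g$atoms))
  if (nrow(g$bonds) > 0) {
    for (k in seq_len(nrow(g$bonds))) {
      a <- g$bonds$a[k]; b <- g$bonds$b[k]; o <- g$bonds$order[k]
      nb_sum[a] <- nb_sum[a] + ord_num[[o]]
      nb_sum[b] <- nb_sum[b] + ord_num[[o]]
      if (o %in% c("2", "3")) has_multi[a] <- has_multi[b] <- TRUE
    }
  }
  h <- g$atoms$hcount
  for (i in seq_len(nrow(g$atoms))) {
    if (!is.na(h[i])) next
    # pi increment only for aromatic C/N/B/P: aromatic O/S contribute a lone
    # pair, not a bond, so their sigma count is the full story
    incr <- g$atoms$aromatic[i] && !has_multi[i] &&
      g$atoms$element[i] %in% c("C", "N", "B", "P")
    used <- nb_sum[i] + (if (incr) 1L else 0L)
    v <- .charged_valence(g$atoms$element[i], g$atoms$charge[i])
    if (is.null(v)) { h[i] <- 0L; next }
    v <- v[v >= used]
    h[i] <- if (length(v) == 0L) 0L else max(0L, min(v) - used)
  }
  g$atoms$hcount <- h
  g
}

#' Normalize charge-separated nitro groups
#'
#' Rewrites \code{-[N+](=O)[O-]} as the uncharged pentavalent form
#' \code{-N(=O)=O}: both N-O bonds become order 2 and the formal charges are
#' cleared.  The two nitro oxygens are chemically equivalent (the charge
#' separation is an artifact of the valence-bond drawing), and after
#' normalization both present the same doubly-bonded acceptor oxygen.
#'
#' @param g a [molgraph].
#' @return the modified graph.
#' @export
normalize_nitro <- function(g) {
  adj <- molgraph_adjacency(g)
  for (i in seq_len(nrow(g$atoms))) {
    if (g$atoms$element[i] != "N" || g$atoms$charge[i] != 1L) next
    nb <- adj[[i]]
    os <- nb[g$atoms$element[nb] == "O"]
    if (length(os) < 2L) next
    dbl <- om <- NA_integer_
    for (o in os) {
      k <- which((g$bonds$a == i & g$bonds$b == o) | (g$bonds$b == i & g$bonds$a == o))
      if (g$bonds$order[k[1]] == "2" && g$atoms$charge[o] == 0L) dbl <- o
      if (g$bonds$order[k[1]] == "1" && g$atoms$charge[o] == -1L) om <- k[1]
    }
    if (!is.na(dbl) && !is.na(om)) {
      g$bonds$order[om] <- "2"
      oidx <- setdiff(c(g$bonds$a[om], g$bonds$b[om]), i)
      g$atoms$charge[oidx] <- 0L
      g$atoms$charge[i] <- 0L
    }
  }
  attr(g, "adjacency") <- NULL
  g
}
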