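# Independent oracles used by the property tests.  These deliberately share
# no code with the production path: brute-force enumeration over the raw
# bond list.

# all simple paths between two atoms, as lists of intermediate atom indices
oracle_simple_paths <- function(g, a, b) {
  adj <- lapply(seq_len(nrow(g$atoms)), function(i)
    c(g$bonds$b[g$bonds$a == i], g$bonds$a[g$bonds$b == i]))
  paths <- list()
  walk <- function(v, seen) {
    for (w in adj[[v]]) {
      if (w == b) {
        paths[[length(paths) + 1L]] <<- setdiff(seen, a)
      } else if (!w %in% seen) {
        walk(w, c(seen, w))
      }
    }
  }
  walk(a, a)
  paths
}

# carbon-chain path test by exhaustive enumeration
oracle_carbon_path <- function(g, a, b) {
  any(vapply(oracle_simple_paths(g, a, b), function(mid)
    all(g$atoms$element[mid] == "C"), logical(1)))
}

# structural invariant bundle used as a practical isomorphism check
graph_invariants <- function(g) {
  deg <- integer(nrow(g$atoms))
  for (k in seq_len(nrow(g$bonds))) {
    deg[g$bonds$a[k]] <- deg[g$bonds$a[k]] + 1L
    deg[g$bonds$b[k]] <- deg[g$bonds$b[k]] + 1L
  }
  at <- sort(paste0(g$atoms$element, "/", g$atoms$charge, "/",
                    as.integer(g$atoms$aromatic), "/", g$atoms$hcount, "/", deg))
  ends <- cbind(paste0(g$atoms$element[g$bonds$a], deg[g$bonds$a]),
                paste0(g$atoms$element[g$bonds$b], deg[g$bonds$b]))
  bd <- sort(paste0(pmin(ends[, 1], ends[, 2]), "~",
                    pmax(ends[, 1], ends[, 2]), "~", g$bonds$order))
  list(formula = molgraph_formula(g), atoms = at, bonds = bd)
}

# random atom-order permutation via the SMILES writer
permuted_graph <- function(g, seed) {
  set.seed(seed)
  parse_smiles(write_smiles(g, order = sample(nrow(g$atoms))))
}

fixture_path <- function() {
  system.file("extdata", "azolopyrimidines_tt_synthetic.csv",
              package = "azolopharm", mustWork = TRUE)
}
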