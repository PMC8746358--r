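test_that("carbon path test matches the worked cases", {
  eta <- parse_smiles("NCCO")               # ethanolamine N-C-C-O
  expect_true(carbon_path_exists(eta, 1, 4))
  hyd <- parse_smiles("NO")                 # direct bond, zero intermediates
  expect_true(carbon_path_exists(hyd, 1, 2))
  blk <- parse_smiles("NOCO")               # H2N-O-CH2-OH: every path crosses O
  expect_false(carbon_path_exists(blk, 1, 4))
  expect_equal(oracle_carbon_path(blk, 1, 4), FALSE)
  expect_error(carbon_path_exists(eta, 2, 2), "invalid")
})

test_that("production path test equals exhaustive enumeration on small graphs", {
  mols <- c("NOCO", "NCCO", "Nc1ccc(O)cc1", "OCC1CCC(N)O1",
            "N1CC1COC", "c1cc(N)oc1C=O", "NC(=O)c1ccncc1")
  for (s in mols) {
    g <- parse_smiles(s)
    n <- nrow(g$atoms)
    stopifnot(n <= 12)
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      expect_equal(carbon_path_exists(g, a, b), oracle_carbon_path(g, a, b),
                   info = sprintf("%s %d-%d", s, a, b))
    }
  }
})

test_that("QL enumeration reproduces brute-force counts on 4-aminophenol", {
  counts <- enumerate_ql_descriptors(parse_smiles("Nc1ccc(O)cc1"))
  expect_equal(unname(counts[ql_label("NH2", "-OH")]), 1L)
  expect_gte(counts[ql_label("NH2", "CycAr06")], 1L)
  expect_gte(counts[ql_label("-OH", "CycAr06")], 1L)
})

test_that("degenerate molecules give empty descriptor maps", {
  expect_length(enumerate_ql_descriptors(parse_smiles("C")), 0)
  expect_length(enumerate_ql_descriptors(parse_smiles("O")), 0)
})

test_that("descriptor labels are unordered and sorted", {
  expect_equal(ql_label("B", "A"), ql_label("A", "B"))
  expect_equal(ql_label("-N=", "=O"), "{-N= ... =O}")
})

test_that("nitro group pairs with its nitrogen once under merged oxygens", {
  counts <- enumerate_ql_descriptors(parse_smiles("[O-][N+](=O)c1ccco1"))
  expect_equal(unname(counts[ql_label("-N=", "=O")]), 1L)
  # with merging off both oxygens pair separately
  counts2 <- enumerate_ql_descriptors(parse_smiles("[O-][N+](=O)c1ccco1"),
                                      fragment_catalog(merge_geminal_o = FALSE))
  expect_equal(unname(counts2[ql_label("-N=", "=O")]), 2L)
})

test_that("descriptor counts are invariant to atom input order", {
  mols <- c("CCOC(=O)c1c[nH]c2nc(C(=O)OCC)nn2c1=O",
            "O=c1n2nc(-c3ccco3)nc2[nH]cc1[N+](=O)[O-]",
            "Nc1ccc(O)cc1")
  for (s in mols) {
    g <- parse_smiles(s)
    ref <- enumerate_ql_descriptors(g)
    for (perm in 1:17) {
      g2 <- permuted_graph(g, seed = perm)
      expect_identical(enumerate_ql_descriptors(g2), ref,
                       info = sprintf("%s perm %d", s, perm))
    }
  }
})

test_that("a stripped counterion never changes descriptor counts", {
  base <- "O=c1n2nc(-c3ccco3)nc2[n-]cc1[N+](=O)[O-]"
  lone <- neutralize_parent(parse_smiles(base))
  for (ion in c(".[Na+]", ".[NH4+]", ".c1cc[nH+]cc1")) {
    salty <- neutralize_parent(strip_counterions(parse_smiles(paste0(base, ion))))
    expect_identical(enumerate_ql_descriptors(salty),
                     enumerate_ql_descriptors(lone), info = ion)
  }
})
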