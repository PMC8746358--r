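labels_of <- function(mol, catalog = fragment_catalog())
  vapply(match_fragments(mol, catalog), `[[`, "", "label")

test_that("ring fragments match aromatic 5- and 6-rings", {
  expect_equal(sum(labels_of(parse_smiles("c1ccoc1")) == "CycAr05"), 1)
  expect_equal(sum(labels_of(parse_smiles("c1ccccc1")) == "CycAr06"), 1)
  # fused benzimidazole yields one occurrence of each ring type
  bi <- parse_smiles("c1ccc2[nH]cnc2c1")
  expect_equal(sum(labels_of(bi) == "CycAr05"), 1)
  expect_equal(sum(labels_of(bi) == "CycAr06"), 1)
  # saturated rings match neither
  expect_false(any(grepl("CycAr", labels_of(parse_smiles("C1CCCCC1")))))
})

test_that("branched carbon and methyl follow the calibrated rules", {
  neo <- labels_of(parse_smiles("CC(C)(C)C"))
  expect_equal(sum(neo == ">C(<)"), 1)
  expect_equal(sum(neo == "-CH3"), 4)
  # ethyl ester methylene counts as a branch point under the heavy2 rule
  et <- labels_of(parse_smiles("CCOC(C)=O"))
  expect_equal(sum(et == ">C(<)"), 1)
  # but not under the stricter carbon2 rule
  et2 <- labels_of(parse_smiles("CCOC(C)=O"), fragment_catalog(branch_rule = "carbon2"))
  expect_equal(sum(et2 == ">C(<)"), 0)
})

test_that("nitrogen fragments partition by hydrogen count and hybridization", {
  occ <- match_fragments(parse_smiles("CNC(=N)N(C)C"))  # amidine-like
  lab <- vapply(occ, `[[`, "", "label")
  expect_equal(sum(lab == ">NH"), 1)
  expect_equal(sum(lab == "-N<"), 1)
  expect_equal(sum(lab == "-N="), 1)
  # pyridine N is -N=, pyrrole NH is >NH
  expect_equal(sum(labels_of(parse_smiles("c1ccncc1")) == "-N="), 1)
  expect_equal(sum(labels_of(parse_smiles("c1cc[nH]c1")) == ">NH"), 1)
})

test_that("geminal acceptor oxygens merge into one occurrence", {
  occ <- match_fragments(parse_smiles("[O-][N+](=O)c1ccco1"))
  o <- occ[vapply(occ, `[[`, "", "label") == "=O"]
  expect_length(o, 1)
  expect_length(o[[1]]$atoms, 2)   # both nitro oxygens, one site
  # a lone carbonyl stays a single-atom occurrence
  occ2 <- match_fragments(parse_smiles("CC=O"))
  o2 <- occ2[vapply(occ2, `[[`, "", "label") == "=O"]
  expect_length(o2[[1]]$atoms, 1)
  # merging can be disabled
  occ3 <- match_fragments(parse_smiles("[O-][N+](=O)c1ccco1"),
                          fragment_catalog(merge_geminal_o = FALSE))
  expect_length(occ3[vapply(occ3, `[[`, "", "label") == "=O"], 2)
})

test_that("nitrile, halogen, ether and thioether match", {
  lab <- labels_of(parse_smiles("N#Cc1ccc(F)cc1OC"))
  expect_equal(sum(lab == "CN"), 1)
  expect_equal(sum(lab == "Hal"), 1)
  expect_equal(sum(lab == "-O-"), 1)
  expect_equal(sum(labels_of(parse_smiles("CSC")) == "-S-"), 1)
})

test_that("catalog restriction and the empty-catalog contract", {
  small <- fragment_catalog(labels = c("-CH3", "CycAr06"))
  expect_equal(nrow(small), 2)
  expect_error(fragment_catalog(labels = "no-such-fragment"), "unknown")
  bad <- fragment_catalog()[0, ]
  class(bad) <- c("fragment_catalog", "data.frame")
  expect_error(match_fragments(parse_smiles("CC"), bad), "empty")
})
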